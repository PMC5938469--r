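#' Simulation configuration
#'
#' Parameters of the synthetic study system. Defaults mirror the scale of
#' the New Zealand avian atlas system: pools of 62 native and 25 exotic
#' species and 19 native and 13 exotic habitat types, a 10-km quadrat grid,
#' heterogeneous occupancy, spatially autocorrelated habitat composition
#' and survey effort, and community assembly whose environmental-filtering
#' strength is an explicit tunable parameter.
#'
#' @param n_native_species,n_exotic_species species pool sizes (62/25).
#' @param n_native_habitats,n_exotic_habitats habitat pool sizes (19/13).
#' @param grid_nx,grid_ny quadrat grid dimensions (default 20 x 20).
#' @param cell_km grid spacing in km (default 10).
#' @param filtering_native,filtering_exotic environmental filtering
#'   strength phi (>= 0) per provenance; 0 (default) reduces community
#'   assembly exactly to the occupancy-weighted null process.
#' @param habitat_spatial_range range (km) of the exponential covariance of
#'   the habitat and effort Gaussian fields (default 50).
#' @param effort_log_mean,effort_log_sd log-scale location and spread of
#'   quadrat survey effort (defaults `log(10)` and 0.6: a median of ~10
#'   checklists per quadrat).
#' @param richness_coupling strength of the shared latent richness driver
#'   linking native and exotic occupancy (default 1; induces positive
#'   native-exotic richness correlation).
#' @param occupancy_rate baseline per-species occupancy probability
#'   (default 0.35).
#' @param latent_sd spread of the 3 latent trait axes generating resource
#'   matrices (default 1; 0 removes functional cluster structure).
#' @param occupancy_weight_sd log-scale SD of species' base occupancy
#'   weights (default 0.8; occupancy-frequency heterogeneity).
#' @param sea_border logical: place partially marine quadrats on the grid
#'   border (exercises the sea filter and edge effects).
#' @param sar_lambda,sar_beta,sar_sigma parameters of [gen_sar_response()]
#'   test-bed responses (defaults 0.6, `c(1, 2, -1)`, 1).
#' @param seed master seed; the entire dataset is a pure function of the
#'   configuration.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_native_species = 62L, n_exotic_species = 25L,
                       n_native_habitats = 19L, n_exotic_habitats = 13L,
                       grid_nx = 20L, grid_ny = 20L, cell_km = 10,
                       filtering_native = 0, filtering_exotic = 0,
                       habitat_spatial_range = 50,
                       effort_log_mean = log(10), effort_log_sd = 0.6,
                       richness_coupling = 1, occupancy_rate = 0.35,
                       latent_sd = 1, occupancy_weight_sd = 0.8,
                       sea_border = TRUE,
                       sar_lambda = 0.6, sar_beta = c(1, 2, -1),
                       sar_sigma = 1, seed = 1L) {
  cfg <- list(n_native_species = n_native_species,
              n_exotic_species = n_exotic_species,
              n_native_habitats = n_native_habitats,
              n_exotic_habitats = n_exotic_habitats,
              grid_nx = grid_nx, grid_ny = grid_ny, cell_km = cell_km,
              filtering_native = filtering_native,
              filtering_exotic = filtering_exotic,
              habitat_spatial_range = habitat_spatial_range,
              effort_log_mean = effort_log_mean,
              effort_log_sd = effort_log_sd,
              richness_coupling = richness_coupling,
              occupancy_rate = occupancy_rate,
              latent_sd = latent_sd,
              occupancy_weight_sd = occupancy_weight_sd,
              sea_border = sea_border,
              sar_lambda = sar_lambda, sar_beta = sar_beta,
              sar_sigma = sar_sigma, seed = as.integer(seed))
  with(cfg, stopifnot(
    n_native_species >= 2L, n_exotic_species >= 2L,
    n_native_habitats >= 2L, n_exotic_habitats >= 2L,
    grid_nx >= 2L, grid_ny >= 2L, cell_km > 0,
    filtering_native >= 0, filtering_exotic >= 0,
    abs(sar_lambda) < 1, sar_sigma > 0))
  structure(cfg, class = "sim_config")
}

# latent-axis mixed binary/ordinal trait values for one component pool
.gen_pool_values <- function(n, schema, latent_sd) {
  Z <- matrix(stats::rnorm(n * 3L, sd = latent_sd), n, 3L)
  vals <- matrix(0L, n, nrow(schema))
  for (k in seq_len(nrow(schema))) {
    load <- stats::rnorm(3L)
    if (schema$kind[k] == "binary") {
      prev <- stats::runif(1L, 0.2, 0.8)
      pr <- stats::plogis(stats::qlogis(prev) + drop(Z %*% load))
      vals[, k] <- stats::rbinom(n, 1L, pr)
    } else {
      base <- stats::runif(1L, -0.5, 1.5)
      score <- base + drop(Z %*% load) + stats::rnorm(n, sd = 0.5)
      vals[, k] <- pmin(3L, pmax(0L, as.integer(round(score))))
    }
  }
  vals
}

#' Generate species and habitat resource matrices
#'
#' Binary categories are Bernoulli with per-category prevalence drawn from
#' (0.2, 0.8); ordinal diet levels arise from three latent trait axes plus
#' noise, rounded into 0--3, so that functional clusters (trait syndromes)
#' exist in both pools. Deterministic given the configuration seed.
#'
#' @param cfg a [sim_config()].
#' @return list with elements `species` and `habitats`, both
#'   [resource_matrix()] objects sharing the default 38-category schema.
#' @export
gen_resource_matrices <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  schema <- default_resource_schema()
  with_seed(derive_seed(cfg$seed, "resources"), {
    n_sp <- cfg$n_native_species + cfg$n_exotic_species
    sp_vals <- .gen_pool_values(n_sp, schema, cfg$latent_sd)
    rownames(sp_vals) <- sprintf("sp%03d", seq_len(n_sp))
    species <- resource_matrix(
      sp_vals,
      rep(c("native", "exotic"), c(cfg$n_native_species, cfg$n_exotic_species)),
      "species", schema)
    n_hb <- cfg$n_native_habitats + cfg$n_exotic_habitats
    hb_vals <- .gen_pool_values(n_hb, schema, cfg$latent_sd)
    rownames(hb_vals) <- sprintf("hb%02d", seq_len(n_hb))
    habitats <- resource_matrix(
      hb_vals,
      rep(c("native", "exotic"), c(cfg$n_native_habitats, cfg$n_exotic_habitats)),
      "habitat", schema)
    list(species = species, habitats = habitats)
  })
}

# grid coordinates (cell centroids, km) and the Cholesky factor of the
# exponential-covariance Gaussian field over them
.grid_field_chol <- function(cfg) {
  xs <- (seq_len(cfg$grid_nx) - 0.5) * cfg$cell_km
  ys <- (seq_len(cfg$grid_ny) - 0.5) * cfg$cell_km
  coords <- as.matrix(expand.grid(x_km = xs, y_km = ys))
  D <- as.matrix(stats::dist(coords))
  Sigma <- exp(-D / cfg$habitat_spatial_range)
  list(coords = coords, U = chol(Sigma + diag(1e-8, nrow(coords))))
}

.grf <- function(U) drop(crossprod(U, stats::rnorm(nrow(U))))

#' Generate the synthetic landscape
#'
#' Per-habitat presence fields are thresholded spatially autocorrelated
#' Gaussian fields (exponential covariance, range
#' `cfg$habitat_spatial_range`), so neighboring quadrats share habitat
#' sets; survey effort is log-normal and spatially smooth; quadrats on the
#' grid border receive sea fractions up to 0.6 (most of them beyond the
#' 10% filter) when `sea_border` is set.
#'
#' @param cfg a [sim_config()].
#' @param habitat_matrix the habitat [resource_matrix()] (supplies ids).
#' @return a [quadrat_table()] with empty species sets.
#' @export
gen_landscape <- function(cfg, habitat_matrix) {
  stopifnot(inherits(cfg, "sim_config"), inherits(habitat_matrix, "resource_matrix"))
  gf <- .grid_field_chol(cfg)
  n <- nrow(gf$coords)
  with_seed(derive_seed(cfg$seed, "landscape"), {
    presence <- sapply(habitat_matrix$ids, function(h) {
      f <- .grf(gf$U)
      prev <- stats::runif(1L, 0.3, 0.7)
      f >= stats::quantile(f, 1 - prev)
    })
    eff_field <- .grf(gf$U)
    eff_field <- (eff_field - mean(eff_field)) / stats::sd(eff_field)
    effort <- pmax(1, round(exp(cfg$effort_log_mean +
                                  cfg$effort_log_sd * eff_field)))
    on_border <- gf$coords[, 1L] %in% range(gf$coords[, 1L]) |
      gf$coords[, 2L] %in% range(gf$coords[, 2L])
    sea <- numeric(n)
    if (cfg$sea_border) sea[on_border] <- stats::runif(sum(on_border), 0, 0.6)
    ids <- sprintf("q%04d", seq_len(n))
    habitats <- stats::setNames(
      lapply(seq_len(n), function(i) habitat_matrix$ids[presence[i, ]]), ids)
    quadrat_table(
      data.frame(id = ids, x_km = gf$coords[, 1L], y_km = gf$coords[, 2L],
                 effort = effort, sea_fraction = sea),
      species = stats::setNames(rep(list(character()), n), ids),
      habitats = habitats)
  })
}

#' Assemble synthetic communities under tunable environmental filtering
#'
#' Species occurrence in a quadrat is a weighted draw without replacement
#' (the same [weighted_sample()] code path as the null model) from the
#' provenance pool, with selection weight
#' `w_s = base_s * exp(phi * overlap_z(s, q))`, where `base_s` is the
#' species' log-normal base occupancy weight and `overlap(s, q)` is one
#' minus the mean cross-pool Gower distance between the species' resource
#' use and the resource availability of the habitats present in the
#' quadrat (z-scored within the pool). With `phi = 0` assembly is exactly
#' the occupancy-weighted null process. Per-quadrat richness is binomial
#' with a logit rate driven by log effort and a shared smooth latent
#' driver whose strength is `richness_coupling` (inducing positive
#' native-exotic richness correlation).
#'
#' @param cfg a [sim_config()].
#' @param species_matrix species [resource_matrix()].
#' @param habitat_matrix habitat [resource_matrix()] (for the overlap term;
#'   only consulted when a filtering strength is positive).
#' @param quadrats a [gen_landscape()] table.
#' @return the [quadrat_table()] with species sets filled in.
#' @export
gen_communities <- function(cfg, species_matrix, habitat_matrix, quadrats) {
  stopifnot(inherits(cfg, "sim_config"),
            inherits(species_matrix, "resource_matrix"),
            inherits(habitat_matrix, "resource_matrix"),
            inherits(quadrats, "quadrat_table"))
  sp <- split_by_provenance(species_matrix)
  gf <- .grid_field_chol(cfg)
  n <- nrow(quadrats$info)
  base_w <- with_seed(derive_seed(cfg$seed, "occupancy"),
                      stats::setNames(stats::rlnorm(length(species_matrix$ids),
                                                    0, cfg$occupancy_weight_sd),
                                      species_matrix$ids))
  driver <- with_seed(derive_seed(cfg$seed, "richness_driver"), {
    f <- .grf(gf$U)
    (f - mean(f)) / stats::sd(f)
  })
  leff <- log(quadrats$info$effort)
  leff_z <- if (stats::sd(leff) > 0) (leff - mean(leff)) / stats::sd(leff) else leff * 0
  phi <- c(native = cfg$filtering_native, exotic = cfg$filtering_exotic)
  # species x habitat resource overlap, shared Gower machinery, computed once
  xg <- if (any(phi > 0)) cross_gower(species_matrix, habitat_matrix) else NULL
  species_sets <- stats::setNames(vector("list", n), quadrats$info$id)
  for (i in seq_len(n)) {
    qid <- quadrats$info$id[i]
    habs <- quadrats$habitats[[qid]]
    chosen <- character()
    for (prov in c("native", "exotic")) {
      pool <- sp[[prov]]
      p_occ <- stats::plogis(stats::qlogis(cfg$occupancy_rate) +
                               0.4 * leff_z[i] +
                               cfg$richness_coupling * driver[i])
      w <- base_w[pool$ids]
      if (phi[[prov]] > 0 && length(habs) > 0) {
        ov <- 1 - rowMeans(xg[pool$ids, habs, drop = FALSE])
        ovz <- if (stats::sd(ov) > 0) (ov - mean(ov)) / stats::sd(ov) else ov * 0
        w <- w * exp(phi[[prov]] * ovz)
      }
      k <- with_seed(derive_seed(cfg$seed, paste0("richness/", prov, "/", qid)),
                     stats::rbinom(1L, length(pool$ids), p_occ))
      if (k > 0L)
        chosen <- c(chosen,
                    with_seed(derive_seed(cfg$seed, paste0("community/", prov, "/", qid)),
                              weighted_sample(w, k)))
    }
    species_sets[[qid]] <- chosen
  }
  out <- quadrat_table(quadrats$info, species_sets, quadrats$habitats)
  attr(out, "base_weights") <- base_w
  out
}

#' Generate a SAR spatial-error response on known parameters
#'
#' `y = X beta + (I - lambda W)^-1 e`, `e ~ N(0, sigma^2 I)`: the test-bed
#' for the SAR fitting machinery, deterministic given the seed.
#'
#' @param X design matrix (intercept included by the caller if wanted).
#' @param w a [build_weights()] object.
#' @param beta coefficient vector (`length(beta) == ncol(X)`).
#' @param lambda spatial error parameter (`|lambda| < 1` for
#'   row-standardized weights).
#' @param sigma innovation SD.
#' @param seed integer seed.
#' @return numeric response vector.
#' @export
gen_sar_response <- function(X, w, beta, lambda, sigma, seed) {
  X <- as.matrix(X)
  stopifnot(inherits(w, "spatial_weights"), ncol(X) == length(beta),
            nrow(X) == w$n)
  eps <- with_seed(seed, stats::rnorm(w$n, 0, sigma))
  drop(X %*% beta + solve(diag(w$n) - lambda * w$W, eps))
}

#' Generate a full synthetic dataset
#'
#' Resource matrices, landscape and communities in one call; every pipeline
#' stage downstream (filtering, FD/sFD, SAR, partitioning) can run on the
#' result with known ground truth.
#'
#' @param cfg a [sim_config()].
#' @return list: `species`, `habitats` ([resource_matrix()]), `quadrats`
#'   ([quadrat_table()]), `occupancy_weights` (the species' generative base
#'   occupancy weights, useful for exact null calibration checks), `config`.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  mats <- gen_resource_matrices(cfg)
  land <- gen_landscape(cfg, mats$habitats)
  comm <- gen_communities(cfg, mats$species, mats$habitats, land)
  list(species = mats$species, habitats = mats$habitats,
       quadrats = comm, occupancy_weights = attr(comm, "base_weights"),
       config = cfg)
}
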