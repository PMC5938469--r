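#' Quadrat table: spatial sampling units with occurrences
#'
#' One row per 10 x 10 km quadrat: id, planar centroid coordinates (km),
#' survey effort (number of species lists, `>= 1`), sea fraction in
#' `[0, 1]`, and the sets of species and habitat ids recorded in it.
#'
#' @param info data.frame with columns `id`, `x_km`, `y_km`, `effort`,
#'   `sea_fraction`.
#' @param species named list (by quadrat id) of species id vectors.
#' @param habitats named list (by quadrat id) of habitat id vectors.
#' @return an object of class `quadrat_table`.
#' @export
quadrat_table <- function(info, species, habitats) {
  stopifnot(is.data.frame(info),
            all(c("id", "x_km", "y_km", "effort", "sea_fraction") %in% names(info)))
  info$id <- as.character(info$id)
  if (anyDuplicated(info$id)) stop_("duplicate quadrat id(s)")
  if (anyDuplicated(info[c("x_km", "y_km")]))
    stop_("duplicate quadrat coordinates")
  if (any(info$effort < 1)) stop_("effort must be >= 1")
  if (any(info$sea_fraction < 0 | info$sea_fraction > 1))
    stop_("sea_fraction must lie in [0, 1]")
  species <- species[info$id]
  habitats <- habitats[info$id]
  if (anyNA(names(species)) || anyNA(names(habitats)))
    stop_("species/habitats lists must cover every quadrat id")
  species <- lapply(species, function(x) unique(as.character(x %||% character())))
  habitats <- lapply(habitats, function(x) unique(as.character(x %||% character())))
  rownames(info) <- NULL
  structure(list(info = info, species = species, habitats = habitats),
            class = "quadrat_table")
}

#' @export
print.quadrat_table <- function(x, ...) {
  cat(sprintf("quadrat_table: %d quadrats, mean richness %.1f species / %.1f habitats\n",
              nrow(x$info), mean(lengths(x$species)), mean(lengths(x$habitats))))
  invisible(x)
}

#' @export
length.quadrat_table <- function(x) nrow(x$info)

# subset a quadrat table by row index or id
subset_quadrats <- function(q, keep) {
  ids <- if (is.character(keep)) keep else q$info$id[keep]
  quadrat_table(q$info[match(ids, q$info$id), , drop = FALSE],
                q$species[ids], q$habitats[ids])
}

#' Read a quadrat table from CSV
#'
#' Wide format: columns `id, x_km, y_km, effort, sea_fraction, species,
#' habitats` with the last two holding semicolon-joined id lists.
#' Alternatively, pass long-format occurrence tables
#' (`quadrat_id, component_id`) via `species_occ`/`habitat_occ` and omit
#' the joined columns.
#'
#' @param path CSV path.
#' @param species_occ,habitat_occ optional paths to long-format occurrence
#'   CSVs.
#' @return a [quadrat_table()].
#' @export
read_quadrat_table <- function(path, species_occ = NULL, habitat_occ = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  split_ids <- function(s) lapply(strsplit(as.character(s), ";", fixed = TRUE),
                                  function(x) x[nzchar(x)])
  get_sets <- function(col, occ_path) {
    if (!is.null(occ_path)) {
      occ <- utils::read.csv(occ_path, stringsAsFactors = FALSE)
      sets <- split(as.character(occ[[2L]]), as.character(occ[[1L]]))
      out <- sets[as.character(df$id)]
      names(out) <- df$id
      out
    } else if (col %in% names(df)) {
      stats::setNames(split_ids(df[[col]]), df$id)
    } else {
      stop_("column '%s' absent and no occurrence file supplied", col)
    }
  }
  quadrat_table(df[c("id", "x_km", "y_km", "effort", "sea_fraction")],
                get_sets("species", species_occ),
                get_sets("habitats", habitat_occ))
}

#' Write a quadrat table to CSV (wide format)
#' @param q a [quadrat_table()].
#' @param path output CSV path.
#' @export
write_quadrat_table <- function(q, path) {
  df <- q$info
  df$species <- vapply(q$species, paste, "", collapse = ";")
  df$habitats <- vapply(q$habitats, paste, "", collapse = ";")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Filter quadrats for analysis
#'
#' Retains quadrats with sea fraction at most `max_sea` (default 10%) and,
#' with the default per-provenance rule, at least `min_components` native
#' and exotic species and native and exotic habitats each (the strictest
#' reading consistent with reported minima of 2 for all four counts). With
#' `per_provenance = FALSE` only total species and habitat counts are
#' checked. Exclusion counts per reason are logged; a quadrat failing both
#' rules is logged under "sea".
#'
#' @param q a [quadrat_table()].
#' @param species_matrix,habitat_matrix [resource_matrix()] objects
#'   supplying the provenance labels.
#' @param max_sea maximum sea fraction (default 0.10).
#' @param min_components minimum components per group (default 2).
#' @param per_provenance apply the minimum per provenance group.
#' @return list: `quadrats` (filtered [quadrat_table()]), `log`
#'   (data.frame of reason/count), `excluded` (id/reason data.frame).
#' @export
filter_quadrats <- function(q, species_matrix, habitat_matrix,
                            max_sea = 0.10, min_components = 2L,
                            per_provenance = TRUE) {
  stopifnot(inherits(q, "quadrat_table"),
            inherits(species_matrix, "resource_matrix"),
            inherits(habitat_matrix, "resource_matrix"))
  sp_prov <- species_matrix$provenance
  hb_prov <- habitat_matrix$provenance
  count_group <- function(sets, prov, p)
    vapply(sets, function(s) sum(prov[s] == p, na.rm = TRUE), 0L)
  n <- nrow(q$info)
  sea_bad <- q$info$sea_fraction > max_sea
  if (per_provenance) {
    comp_bad <- count_group(q$species, sp_prov, "native") < min_components |
      count_group(q$species, sp_prov, "exotic") < min_components |
      count_group(q$habitats, hb_prov, "native") < min_components |
      count_group(q$habitats, hb_prov, "exotic") < min_components
  } else {
    comp_bad <- lengths(q$species) < min_components |
      lengths(q$habitats) < min_components
  }
  reason <- rep(NA_character_, n)
  reason[comp_bad] <- "min_components"
  reason[sea_bad] <- "sea"
  keep <- is.na(reason)
  if (!any(keep)) stop_("no quadrats survive filters")
  log <- as.data.frame(table(reason = reason[!keep]), stringsAsFactors = FALSE)
  names(log) <- c("reason", "count")
  list(quadrats = subset_quadrats(q, which(keep)),
       log = log,
       excluded = data.frame(id = q$info$id[!keep], reason = reason[!keep]))
}

#' Occupancy pool weights
#'
#' Number of quadrats in which each pool component was recorded; the
#' selection weights of the null model.
#'
#' @param q a [quadrat_table()].
#' @param ids pool component ids.
#' @param kind `"species"` or `"habitat"`.
#' @return named integer vector over `ids` (zeros for unrecorded).
#' @export
pool_weights <- function(q, ids, kind = c("species", "habitat")) {
  kind <- match.arg(kind)
  sets <- if (kind == "species") q$species else q$habitats
  tab <- table(unlist(sets, use.names = FALSE))
  w <- stats::setNames(as.numeric(tab[ids]), ids)
  w[is.na(w)] <- 0
  w
}

#' Per-quadrat FD and sFD for the four community/landscape measurements
#'
#' For each quadrat computes observed FD and occurrence-weighted null
#' standardized FD (sFD) for the native community, exotic community, native
#' landscape and exotic landscape: species/habitat pools are split by
#' provenance, one UPGMA dendrogram is built per pool from the full pool
#' (so all quadrats share a common reference), pool weights are the
#' occupancy counts over the supplied quadrats, and each quadrat x pool
#' null distribution runs on its own RNG stream derived from
#' `(seed, quadrat id, pool)` so results are independent of processing
#' order. Quadrats whose null SD is zero get `NA` sFD (flagged count in
#' the `n_undefined_sfd` attribute).
#'
#' @param q a filtered [quadrat_table()].
#' @param species_matrix,habitat_matrix pool [resource_matrix()] objects.
#' @param n_iter null iterations per quadrat and pool (default 1000).
#' @param seed master seed.
#' @param include_root_path FD convention flag ([fd_subset()]).
#' @param pool_trees `"separate"` (default: one dendrogram per provenance
#'   pool) or `"combined"` (a single all-component dendrogram per kind, on
#'   which provenance subsets are measured).
#' @param ranges Gower range normalization, see [gower_distance()].
#' @param weights optional named numeric vector of null selection weights
#'   over component ids (species and/or habitats), overriding the default
#'   occupancy counts computed from `q` — e.g. the generative weights of a
#'   simulation for exact calibration checks. Pool components missing from
#'   the vector fall back to their occupancy count.
#' @return data.frame of class `quadrat_fd`: per quadrat the four richness
#'   counts, four FD values, four sFD values, null means/SDs and the seed;
#'   attributes `trees`, `weights`, `include_root_path`, `n_undefined_sfd`.
#' @export
compute_quadrat_fd <- function(q, species_matrix, habitat_matrix,
                               n_iter = 1000L, seed = 1L,
                               include_root_path = FALSE,
                               pool_trees = c("separate", "combined"),
                               ranges = "observed", weights = NULL) {
  pool_trees <- match.arg(pool_trees)
  stopifnot(inherits(q, "quadrat_table"))
  sp <- split_by_provenance(species_matrix)
  hb <- split_by_provenance(habitat_matrix)
  pools <- list(
    community_native = list(m = sp$native, full = species_matrix, kind = "species", prov = "native"),
    community_exotic = list(m = sp$exotic, full = species_matrix, kind = "species", prov = "exotic"),
    landscape_native = list(m = hb$native, full = habitat_matrix, kind = "habitat", prov = "native"),
    landscape_exotic = list(m = hb$exotic, full = habitat_matrix, kind = "habitat", prov = "exotic"))
  trees <- lapply(pools, function(p) {
    src <- if (pool_trees == "combined") p$full else p$m
    if (is.null(src) || length(src$ids) < 2L)
      stop_("pool %s/%s has < 2 components", p$kind, p$prov)
    upgma(gower_distance(src, ranges = ranges))
  })
  override <- weights
  weights <- lapply(pools, function(p) {
    w <- pool_weights(q, p$m$ids, kind = p$kind)
    if (!is.null(override)) {
      hit <- p$m$ids %in% names(override)
      w[hit] <- override[p$m$ids[hit]]
    }
    w
  })

  # every recorded id must belong to its pool tree
  for (nm in c("species", "habitat")) {
    sets <- if (nm == "species") q$species else q$habitats
    pool_ids <- if (nm == "species") species_matrix$ids else habitat_matrix$ids
    unknown <- setdiff(unique(unlist(sets, use.names = FALSE)), pool_ids)
    if (length(unknown))
      stop_("%s id(s) absent from the pool matrix: %s", nm,
            paste(unknown, collapse = ", "))
  }

  ids <- q$info$id
  out <- q$info[c("id", "x_km", "y_km", "effort", "sea_fraction")]
  membership <- function(p, qid) {
    set <- if (p$kind == "species") q$species[[qid]] else q$habitats[[qid]]
    intersect(set, p$m$ids)
  }
  n_undef <- 0L
  for (pool in names(pools)) {
    p <- pools[[pool]]
    tr <- trees[[pool]]
    w <- weights[[pool]]
    kcol <- fdcol <- sfdcol <- mucol <- sdcol <- numeric(length(ids))
    for (i in seq_along(ids)) {
      present <- membership(p, ids[i])
      k <- length(present)
      kcol[i] <- k
      if (k == 0L) {
        fdcol[i] <- 0
        sfdcol[i] <- mucol[i] <- sdcol[i] <- NA_real_
        next
      }
      fdcol[i] <- fd_subset(tr, present, include_root_path)
      nd <- null_fd_distribution(tr, w, k, n_iter = n_iter,
                                 include_root_path = include_root_path,
                                 seed = derive_seed(seed, paste0(ids[i], "/", pool)),
                                 pool_id = pool)
      s <- standardize_fd(fdcol[i], nd)
      sfdcol[i] <- s$sfd
      mucol[i] <- nd$mean_fd
      sdcol[i] <- nd$sd_fd
      if (s$undefined) n_undef <- n_undef + 1L
    }
    out[[if (p$kind == "species") paste0("richness_", p$prov)
         else paste0("n_", p$prov, "_habitats")]] <- as.integer(kcol)
    out[[paste0("fd_", pool)]] <- fdcol
    out[[paste0("sfd_", pool)]] <- sfdcol
    out[[paste0("null_mean_", pool)]] <- mucol
    out[[paste0("null_sd_", pool)]] <- sdcol
  }
  out$seed <- rep(as.integer(seed), length(ids))
  structure(out, class = c("quadrat_fd", "data.frame"),
            trees = trees, weights = weights,
            include_root_path = include_root_path,
            n_iter = as.integer(n_iter), n_undefined_sfd = n_undef)
}

#' Pearson correlation report over quadrat FD fields
#'
#' Pairwise Pearson correlations (two-sided t approximation) between named
#' columns of a [compute_quadrat_fd()] table, on complete cases per pair.
#' Zero-variance pairs are flagged with `NA` rather than an error.
#'
#' @param fd a `quadrat_fd` data.frame.
#' @param pairs list of character 2-vectors naming column pairs.
#' @return data.frame: `var1`, `var2`, `r`, `n`, `p_value`.
#' @export
correlation_report <- function(fd, pairs) {
  stopifnot(is.data.frame(fd), length(pairs) >= 1L)
  rows <- lapply(pairs, function(pr) {
    stopifnot(length(pr) == 2L, all(pr %in% names(fd)))
    x <- fd[[pr[1L]]]; y <- fd[[pr[2L]]]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3L) stop_("fewer than 3 complete cases for %s ~ %s", pr[1L], pr[2L])
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
      return(data.frame(var1 = pr[1L], var2 = pr[2L], r = NA_real_,
                        n = sum(ok), p_value = NA_real_))
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
    data.frame(var1 = pr[1L], var2 = pr[2L], r = unname(ct$estimate),
               n = sum(ok), p_value = ct$p.value)
  })
  do.call(rbind, rows)
}
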