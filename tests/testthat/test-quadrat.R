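make_filter_table <- function() {
  # five quadrats: q2 too marine, q4 has one native species only
  info <- data.frame(id = paste0("q", 1:5),
                     x_km = seq(5, 45, 10), y_km = 5,
                     effort = c(3, 5, 2, 8, 4),
                     sea_fraction = c(0, 0.11, 0.10, 0.02, 0))
  sp <- list(q1 = c("A", "B", "D", "E"), q2 = c("A", "B", "D", "E"),
             q3 = c("B", "C", "D", "E"), q4 = c("A", "D", "E"),
             q5 = c("A", "C", "D", "E"))
  hb <- list(q1 = c("h1", "h2", "h3", "h4"), q2 = c("h1", "h2", "h3", "h4"),
             q3 = c("h1", "h2", "h3", "h4"), q4 = c("h1", "h2", "h3", "h4"),
             q5 = c("h1", "h2", "h3", "h4"))
  quadrat_table(info, sp, hb)
}

test_that("quadrat filters apply the sea and per-provenance minimum rules", {
  sys <- toy_system()
  q <- make_filter_table()
  fl <- filter_quadrats(q, sys$species, sys$habitats)
  expect_setequal(fl$quadrats$info$id, c("q1", "q3", "q5"))
  lg <- stats::setNames(fl$log$count, fl$log$reason)
  expect_equal(lg[["sea"]], 1L)           # q2: sea_fraction 0.11 > 0.10
  expect_equal(lg[["min_components"]], 1L) # q4: one native species
  expect_equal(fl$excluded$reason[fl$excluded$id == "q2"], "sea")
  expect_equal(fl$excluded$reason[fl$excluded$id == "q4"], "min_components")
  # boundary: sea_fraction exactly 0.10 is retained (q3)
  expect_true("q3" %in% fl$quadrats$info$id)
  # laxer total-count interpretation keeps q4
  fl2 <- filter_quadrats(q, sys$species, sys$habitats, per_provenance = FALSE)
  expect_true("q4" %in% fl2$quadrats$info$id)
  # empty survivors error
  qi <- q$info; qi$sea_fraction <- 0.5
  allsea <- quadrat_table(qi, q$species, q$habitats)
  expect_error(filter_quadrats(allsea, sys$species, sys$habitats),
               "no quadrats survive")
})

test_that("pool weights are occupancy counts", {
  q <- make_filter_table()
  w <- pool_weights(q, c("A", "B", "C", "Z"), "species")
  expect_equal(unname(w), c(4, 3, 2, 0))
})

test_that("quadrat FD table reproduces hand values and is deterministic", {
  sys <- toy_system()
  fd <- compute_quadrat_fd(sys$quadrats, sys$species, sys$habitats,
                           n_iter = 50, seed = 3)
  # q1's native community is {B, C}: hand tree FD = 8/9
  expect_equal(fd$fd_community_native[fd$id == "q1"], 8 / 9, tolerance = 1e-12)
  # q3 holds the entire native pool: FD = total tree length, sFD undefined
  expect_equal(fd$fd_community_native[fd$id == "q3"], 2, tolerance = 1e-12)
  expect_true(is.na(fd$sfd_community_native[fd$id == "q3"]))
  expect_gte(attr(fd, "n_undefined_sfd"), 1L)
  # richness bookkeeping matches the id sets
  expect_equal(fd$richness_native, c(2L, 2L, 3L))
  expect_equal(fd$richness_exotic, c(2L, 2L, 2L))
  expect_equal(fd$n_native_habitats, rep(2L, 3))
  # per-quadrat seeding: identical rerun, row order irrelevant
  fd2 <- compute_quadrat_fd(sys$quadrats, sys$species, sys$habitats,
                            n_iter = 50, seed = 3)
  expect_identical(fd, fd2)
  # FD columns are non-negative; every filtered quadrat is present
  expect_true(all(fd$fd_community_native >= 0))
  expect_equal(nrow(fd), 3L)
})

test_that("occurrences missing from the pool matrix raise a named error", {
  sys <- toy_system()
  q <- sys$quadrats
  q$species$q1 <- c(q$species$q1, "ghost")
  expect_error(compute_quadrat_fd(q, sys$species, sys$habitats,
                                  n_iter = 10, seed = 1), "ghost")
})

test_that("explicit null weights override occupancy counts", {
  sys <- toy_system()
  w <- c(A = 5, B = 1, C = 1, D = 1, E = 1, h1 = 1, h2 = 1, h3 = 1, h4 = 1)
  fd_a <- compute_quadrat_fd(sys$quadrats, sys$species, sys$habitats,
                             n_iter = 200, seed = 3, weights = w)
  fd_b <- compute_quadrat_fd(sys$quadrats, sys$species, sys$habitats,
                             n_iter = 200, seed = 3)
  # same observed FD, different null means under different weights
  expect_equal(fd_a$fd_community_native, fd_b$fd_community_native)
  expect_false(isTRUE(all.equal(fd_a$null_mean_community_native[1],
                                fd_b$null_mean_community_native[1])))
})

test_that("correlation report matches hand Pearson values", {
  df <- data.frame(a = c(1, 2, 3), b = c(2, 4, 7), c = c(3, 2, 1),
                   k = c(1, 1, 1))
  rep <- correlation_report(df, list(c("a", "a"), c("a", "c"), c("a", "b")))
  expect_equal(rep$r, c(1, -1, 0.99339927), tolerance = 1e-6)
  expect_equal(rep$n, rep(3L, 3))
  # zero-variance pair flagged, not an error
  repk <- correlation_report(df, list(c("a", "k")))
  expect_true(is.na(repk$r))
  expect_error(correlation_report(df[1:2, ], list(c("a", "b"))), "complete cases")
})

test_that("quadrat CSV round-trips through wide and long formats", {
  sys <- toy_system()
  path <- withr::local_tempfile(fileext = ".csv")
  write_quadrat_table(sys$quadrats, path)
  q2 <- read_quadrat_table(path)
  expect_equal(q2$info, sys$quadrats$info)
  expect_identical(q2$species, sys$quadrats$species)
  expect_identical(q2$habitats, sys$quadrats$habitats)
  # long-format occurrences
  occ <- do.call(rbind, lapply(names(sys$quadrats$species), function(id)
    data.frame(quadrat_id = id, component_id = sys$quadrats$species[[id]])))
  opath <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(occ, opath, row.names = FALSE)
  q3 <- read_quadrat_table(path, species_occ = opath)
  expect_identical(q3$species, sys$quadrats$species)
})
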