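test_that("edge bookkeeping: n(n-1)/2 pairs, 703 at 38 ROIs", {
  s <- build_schedule(n_runs = 1)
  for (p in c(3, 5, 9)) {
    set.seed(p)
    m <- matrix(rnorm(s$n_volumes * p), ncol = p)
    colnames(m) <- paste0("r", seq_len(p))
    bc <- blockwise_correlations(m, s)
    expect_equal(nrow(bc), 3 * p * (p - 1) / 2)
  }
  expect_equal(38 * 37 / 2, 703)
  x <- cohort_roi(simulate_cohort(cohort_spec(
    schedule = build_schedule(n_runs = 1))), "sub01")
  bc38 <- blockwise_correlations(x, build_schedule(n_runs = 1))
  expect_equal(nrow(bc38), 3 * 703)
})

test_that("correlations behave on identical, constant and white series", {
  s <- build_schedule(n_runs = 1)
  a <- rnorm(s$n_volumes)
  m <- cbind(A = a, B = a, C = 1)
  bc <- blockwise_correlations(m, s)
  ab <- bc[bc$roi_i == "A" & bc$roi_j == "B", ]
  expect_true(all(abs(ab$r - 1) < 1e-12))
  expect_true(all(is.na(bc$r[bc$roi_j == "C"])))      # zero variance flagged

  # sampling oracle: white series, Up segments have 28 volumes after trim
  s10 <- build_schedule()
  set.seed(8)
  w <- matrix(rnorm(650 * 20), ncol = 20)
  colnames(w) <- paste0("r", 1:20)
  bcw <- blockwise_correlations(w, s10)
  up_r <- bcw$r[bcw$block == "Upregulation"]
  expect_lt(abs(mean(up_r)), 3 * sd(up_r) / sqrt(length(up_r)))
  expect_equal(sd(up_r), 1 / sqrt(27), tolerance = 0.1)
})

test_that("blockwise correlations are invariant to ROI permutation", {
  s <- build_schedule(n_runs = 1)
  set.seed(9)
  m <- matrix(rnorm(s$n_volumes * 4), ncol = 4)
  colnames(m) <- c("a", "b", "c", "d")
  bc1 <- blockwise_correlations(m, s)
  bc2 <- blockwise_correlations(m[, c(3, 1, 4, 2)], s)
  key <- function(b) paste(b$run, b$block, pmin(b$roi_i, b$roi_j),
                           pmax(b$roi_i, b$roi_j))
  expect_equal(bc1$r[order(key(bc1))], bc2$r[order(key(bc2))],
               tolerance = 1e-12)
})

test_that("edge tests reproduce the published df and control the null", {
  # constructed run-block z differences with the published design counts
  set.seed(10)
  mk <- function(ids, group) do.call(rbind, lapply(ids, function(id)
    expand.grid(subject = id, group = group, run = 1:10,
                block = c("Upregulation", "View"), roi_i = "A", roi_j = "B",
                stringsAsFactors = FALSE)))
  bc <- rbind(mk(sprintf("e%02d", 1:18), "experimental"),
              mk(sprintf("c%02d", 1:14), "control"))
  bc$z <- rnorm(nrow(bc), ifelse(bc$block == "Upregulation" &
                                   bc$group == "experimental", 0.4, 0), 0.2)
  st <- edge_condition_tests(bc)
  expect_equal(st$df_condition, 179)
  expect_equal(st$df_group, 318)
  expect_true(st$survives)

  # fully null reduced cohorts: surviving-edge fraction stays below q
  frac <- vapply(1:20, function(seed) {
    co <- simulate_cohort(null_cohort_spec(master_seed = seed))
    stn <- edge_condition_tests(cohort_blockwise_correlations(co))
    mean(stn$survives)
  }, 0)
  expect_lte(mean(frac), 0.05)
})

test_that("planted differential edges are recovered at cohort scale", {
  spec <- cohort_spec(schedule = build_schedule(),
                      n_experimental = 8, n_control = 8,
                      roi = roi_effect_table()[1:16, ],   # includes caudate
                      delta_edges = data.frame(
                        roi_i = c("L_amygdala", "L_thalamus"),
                        roi_j = c("L_thalamus", "L_caudate"),
                        delta_r = 0.3),
                      master_seed = 21)
  co <- simulate_cohort(spec)
  st <- edge_condition_tests(cohort_blockwise_correlations(co))
  nw <- differential_network(st, nodes = spec$roi$roi)
  planted <- c("L_amygdala|L_thalamus", "L_caudate|L_thalamus")
  got <- paste(pmin(nw$edges$roi_i, nw$edges$roi_j),
               pmax(nw$edges$roi_i, nw$edges$roi_j), sep = "|")
  expect_gte(length(intersect(got, planted)), 1)
  expect_lte(length(setdiff(got, planted)), 3)
  expect_true(all(nw$edges$weight[got %in% planted] > 0))  # sign-consistent
})

test_that("network export round-trips, empty networks allowed", {
  st <- structure(data.frame(roi_i = c("A", "A"), roi_j = c("B", "C"),
                             survives = c(TRUE, FALSE),
                             weight = c(0.4, 0.1)),
                  class = c("nf_edge_stats", "data.frame"), q = 0.05)
  nw <- differential_network(st)
  expect_equal(nrow(nw$edges), 1)
  base <- file.path(withr::local_tempdir(), "net")
  write_network(nw, base)
  back <- read_network(base)
  expect_equal(back$edges, nw$edges)
  expect_equal(back$nodes, nw$nodes)

  st0 <- st; st0$survives <- FALSE
  class(st0) <- class(st); attr(st0, "q") <- 0.05
  nw0 <- differential_network(st0)
  expect_equal(nrow(nw0$edges), 0)
  write_network(nw0, base)
  expect_equal(nrow(read_network(base)$edges), 0)
})

test_that("connectivity distributions show the planted Upregulation shift", {
  s <- build_schedule()
  de <- data.frame(roi_i = "A", roi_j = "B", delta_r = 0.3)
  x <- simulate_roi_bold(s, tiny_roi(), delta_edges = de, seed = 30)
  bc <- blockwise_correlations(x, s)
  nw <- structure(list(nodes = c("A", "B"),
                       edges = data.frame(roi_i = "A", roi_j = "B",
                                          weight = 0.3), q = 0.05),
                  class = "nf_network")
  cd <- connectivity_distributions(bc, nw)
  expect_gt(cd$summary$mean_r[cd$summary$block == "Upregulation"],
            cd$summary$mean_r[cd$summary$block == "View"])
  expect_s3_class(cd$shift, "nf_test")

  empty <- structure(list(nodes = "A",
                          edges = data.frame(roi_i = character(0),
                                             roi_j = character(0),
                                             weight = numeric(0)), q = 0.05),
                     class = "nf_network")
  cd0 <- connectivity_distributions(bc, empty)
  expect_null(cd0$shift)
})
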