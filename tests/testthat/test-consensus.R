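test_that("base clusterers split clean blobs and honor edge cases", {
  d <- blob_distance(n_per = 6, seed = 2)
  truth <- rep(1:2, each = 6)
  for (m in c("pam", "hierarchical_average")) {
    labs <- base_cluster(d, 2, m)
    expect_true(same_partition(labs, truth))
    expect_setequal(unique(labs), 1:2)
  }
  # k = n puts every subject in its own cluster
  expect_equal(base_cluster(d, 12, "pam"), 1:12)
  expect_error(base_cluster(d, 13, "pam"), "exceeds")
  # determinism
  expect_identical(base_cluster(d, 3, "pam"), base_cluster(d, 3, "pam"))
})

test_that("PAM matches exhaustive 2-partition minimization on small instances", {
  for (seed in 1:5) {
    set.seed(seed)
    x <- c(rnorm(5, 0, 0.4), rnorm(5, 3, 0.4))
    d <- abs(outer(x, x, "-"))
    labs <- base_cluster(d, 2, "pam")
    expect_true(same_partition(labs, best_bipartition_oracle(d)))
  }
})

test_that("with full subsampling the consensus is exactly the single-shot partition", {
  d <- blob_distance(n_per = 6, seed = 3)
  cfg <- consensus_config(k_min = 2, k_max = 4, n_iterations = 10,
                          subsample_fraction = 1, seed = 5)
  run <- suppressMessages(run_consensus(d, cfg))
  for (k in 2:4) {
    M <- run$runs[[as.character(k)]]$matrix$values
    expect_true(all(M %in% c(0, 1)))
    expect_equal(diag(M), rep(1, 12), ignore_attr = TRUE)
    expect_equal(M, t(M))
    single <- base_cluster(d, k, "pam")
    expect_true(same_partition(run$runs[[as.character(k)]]$assignment$labels, single))
  }
})

test_that("well-separated blobs give consensus 1 within and 0 between", {
  d <- blob_distance(n_per = 10, gap = 5, seed = 7)
  cfg <- consensus_config(k_min = 2, k_max = 2, n_iterations = 50,
                          subsample_fraction = 0.8, seed = 11)
  run <- suppressMessages(run_consensus(d, cfg))
  M <- run$runs[["2"]]$matrix$values
  blob <- rep(1:2, each = 10)
  same_blob <- outer(blob, blob, "==")
  expect_true(all(M[same_blob] == 1))
  expect_true(all(M[!same_blob] == 0))

  # consensus entries are ratios of co-clustering to co-sampling counts
  counts <- run$runs[["2"]]$matrix$cosample_counts
  expect_true(all(counts[upper.tri(counts)] <= 50))
  expect_equal(run$runs[["2"]]$assignment$sizes, c(10, 10))
})

test_that("consensus runs are reproducible and validate their inputs", {
  d <- blob_distance(n_per = 8, seed = 9)
  cfg <- consensus_config(k_min = 2, k_max = 3, n_iterations = 20, seed = 13)
  r1 <- suppressMessages(run_consensus(d, cfg))
  r2 <- suppressMessages(run_consensus(d, cfg))
  expect_identical(r1$runs[["3"]]$matrix$values, r2$runs[["3"]]$matrix$values)
  expect_identical(r1$runs[["3"]]$assignment$labels, r2$runs[["3"]]$assignment$labels)

  expect_error(consensus_config(k_min = 1), "k_min")
  expect_error(consensus_config(subsample_fraction = 0), "subsample_fraction")
  expect_error(consensus_config(pac_lower = 0.9, pac_upper = 0.1), "pac")
  tiny <- structure(list(values = matrix(0, 5, 5), subject_id = paste0("S", 1:5)),
                    class = "distance_matrix")
  expect_error(suppressMessages(run_consensus(tiny, consensus_config())), "n >= k_max")
})

test_that("clusters are renumbered by descending size", {
  # three blobs of sizes 3, 5, 7 on a line
  set.seed(15)
  x <- c(rnorm(3, 0, 0.01), rnorm(5, 1, 0.01), rnorm(7, 2, 0.01))
  d <- structure(list(values = abs(outer(x, x, "-")),
                      subject_id = paste0("S", 1:15)), class = "distance_matrix")
  cfg <- consensus_config(k_min = 2, k_max = 3, n_iterations = 20,
                          subsample_fraction = 1, seed = 3)
  run <- suppressMessages(run_consensus(d, cfg))
  a <- run$runs[["3"]]$assignment
  expect_equal(a$sizes, c(7, 5, 3))
  expect_equal(unique(a$labels[x > 1.5]), 1)
  expect_equal(unique(a$labels[x < 0.5]), 3)
})

fake_cm <- function(M, k) {
  structure(list(values = M, cosample_counts = matrix(10, nrow(M), nrow(M)), k = k),
            class = "consensus_matrix")
}

test_that("PAC and within-cluster consensus match brute-force pair enumeration", {
  cfg <- consensus_config()
  for (seed in 1:5) {
    set.seed(seed)
    n <- 10
    M <- matrix(runif(n * n), n)
    M <- (M + t(M)) / 2
    diag(M) <- 1
    diag_out <- suppressMessages(compute_diagnostics(list(fake_cm(M, 2), fake_cm(M, 3)), cfg))
    for (row in 1:2) {
      k <- diag_out$summary$k[row]
      expect_equal(diag_out$summary$pac[row], pac_oracle(M, 0.1, 0.9), tolerance = 1e-12)
      labs <- txclust:::consensus_assignment(M, k)$labels
      for (c_idx in seq_len(k)) {
        expect_equal(diag_out$cluster_consensus[[row]][c_idx],
                     suppressMessages(cluster_consensus_oracle(M, labs, c_idx)),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("PAC boundary cases behave as defined", {
  cfg <- consensus_config()
  n <- 8
  hard <- matrix(sample(c(0, 1), n * n, TRUE), n)
  hard <- 1 * ((hard + t(hard)) > 0)
  diag(hard) <- 1
  out <- suppressMessages(compute_diagnostics(list(fake_cm(hard, 2), fake_cm(hard, 3)), cfg))
  expect_equal(out$summary$pac, c(0, 0)) # all values in {0,1}: nothing ambiguous

  soft <- matrix(0.5, n, n)
  diag(soft) <- 1
  out <- suppressMessages(compute_diagnostics(list(fake_cm(soft, 2), fake_cm(soft, 3)), cfg))
  expect_equal(out$summary$pac, c(1, 1)) # everything ambiguous

  # 10 off-diagonal pairs of which 3 fall inside the band
  vals <- c(0.5, 0.3, 0.7, rep(0, 7))
  M <- matrix(0, 5, 5)
  M[upper.tri(M)] <- vals
  M <- M + t(M)
  diag(M) <- 1
  out <- suppressMessages(compute_diagnostics(list(fake_cm(M, 2), fake_cm(M, 3)), cfg))
  expect_equal(out$summary$pac[1], 0.3)
})

test_that("sharpening consensus values toward {0,1} never increases PAC", {
  cfg <- consensus_config()
  for (seed in 1:10) {
    set.seed(seed)
    n <- 12
    M <- matrix(runif(n * n), n); M <- (M + t(M)) / 2; diag(M) <- 1
    sharp <- 1 * (M >= 0.5); diag(sharp) <- 1
    pac_raw <- pac_oracle(M, 0.1, 0.9)
    pac_sharp <- pac_oracle(sharp, 0.1, 0.9)
    expect_lte(pac_sharp, pac_raw)
  }
})

test_that("CDF curves are proper distribution functions and areas follow the trapezoid rule", {
  set.seed(3)
  n <- 15
  M <- matrix(runif(n * n), n); M <- (M + t(M)) / 2; diag(M) <- 1
  out <- suppressMessages(compute_diagnostics(list(fake_cm(M, 2), fake_cm(M, 3)),
                                              consensus_config()))
  for (curve in out$cdf) {
    expect_true(all(diff(curve$cdf) >= 0))
    expect_equal(curve$cdf[nrow(curve)], 1)
  }
  # delta area at k_min is the area itself; next entry is the relative change
  a <- out$summary$cdf_area
  expect_equal(out$summary$delta_area[1], a[1])
  expect_equal(out$summary$delta_area[2], (a[2] - a[1]) / a[1])
})

test_that("select_k implements the three rules with smallest-k tie-breaks", {
  fake <- list(summary = data.frame(
    k = 2:6,
    pac = c(0.4, 0.1, 0.2, 0.3, 0.15),
    cdf_area = seq(0.5, 0.9, 0.1),
    delta_area = c(0.5, 0.2, 0.1, 0.05, 0.02),
    mean_cluster_consensus = c(0.7, 0.8, 0.75, 0.8, 0.95)
  ))
  expect_equal(as.integer(select_k(fake, "mean_consensus")), 6)
  expect_equal(as.integer(select_k(fake, "pac")), 3)
  expect_true(!is.null(attr(select_k(fake, "composite"), "criteria")))

  tied <- fake
  tied$summary$mean_cluster_consensus <- c(0.7, 0.9, 0.9, 0.8, 0.8)
  expect_equal(as.integer(select_k(tied, "mean_consensus")), 3)

  one_k <- list(summary = fake$summary[1, ])
  expect_error(select_k(one_k), "at least 2")
})

test_that("consensus outputs round-trip to plot-ready CSV files", {
  d <- blob_distance(n_per = 6, seed = 4)
  cfg <- consensus_config(k_min = 2, k_max = 3, n_iterations = 15, seed = 2)
  run <- suppressMessages(run_consensus(d, cfg))
  diag_out <- suppressMessages(compute_diagnostics(run))
  dir <- withr::local_tempdir()
  write_consensus_results(run, diag_out, dir, chosen_k = 2)
  expect_true(file.exists(file.path(dir, "consensus_k2.csv")))
  expect_true(file.exists(file.path(dir, "diagnostics.csv")))
  expect_true(file.exists(file.path(dir, "cdf.csv")))
  a <- utils::read.csv(file.path(dir, "assignment_k2.csv"))
  expect_equal(nrow(a), 12)
  expect_setequal(unique(a$cluster), 1:2)
})
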