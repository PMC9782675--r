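# Independent brute-force oracles and small fixture builders.
# The oracles deliberately use naive double loops / enumeration so they stay
# independent of the implementation paths they check.

# tiny mixed-type cohort with known values
toy_cohort <- function() {
  schema <- list(
    age = list(kind = "continuous"),
    bmi = list(kind = "continuous"),
    diabetic = list(kind = "binary", levels = c("no", "yes")),
    race = list(kind = "categorical", levels = c("White", "Black", "Other")),
    band = list(kind = "ordinal", levels = c("low", "mid", "high"))
  )
  data <- data.frame(
    age = c(40, 60, 50, 40),
    bmi = c(20, 30, 25, 20),
    diabetic = c("no", "yes", "no", "no"),
    race = c("White", "Black", "White", "White"),
    band = c("low", "high", "mid", "low"),
    stringsAsFactors = FALSE
  )
  cohort_table(data, schema)
}

# random mixed cohort for property tests
random_cohort <- function(n, seed = 1) {
  set.seed(seed)
  schema <- list(
    x1 = list(kind = "continuous"),
    x2 = list(kind = "continuous"),
    b1 = list(kind = "binary", levels = c("no", "yes")),
    c1 = list(kind = "categorical", levels = c("a", "b", "c")),
    o1 = list(kind = "ordinal", levels = c("l1", "l2", "l3", "l4"))
  )
  data <- data.frame(
    x1 = rnorm(n), x2 = runif(n, 10, 20),
    b1 = sample(c("no", "yes"), n, TRUE),
    c1 = sample(c("a", "b", "c"), n, TRUE),
    o1 = sample(c("l1", "l2", "l3", "l4"), n, TRUE),
    stringsAsFactors = FALSE
  )
  cohort_table(data, schema)
}

# naive Gower: double loop over rows and variables
gower_oracle <- function(cohort, vars = NULL) {
  if (is.null(vars)) vars <- setdiff(names(cohort$data), cohort$admin_vars)
  data <- cohort$data[vars]
  n <- nrow(data)
  kinds <- vapply(cohort$schema[vars], `[[`, "", "kind")
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    acc <- 0
    for (v in vars) {
      if (kinds[[v]] %in% c("continuous", "ordinal")) {
        x <- as.numeric(data[[v]])
        rng <- max(x) - min(x)
        if (rng > 0) acc <- acc + abs(x[i] - x[j]) / rng
      } else {
        if (length(unique(data[[v]])) > 1 && data[[v]][i] != data[[v]][j]) acc <- acc + 1
      }
    }
    D[i, j] <- acc / length(vars)
  }
  D
}

# PAC by direct pair enumeration
pac_oracle <- function(M, lower, upper) {
  n <- nrow(M)
  hits <- 0; total <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    total <- total + 1
    if (M[i, j] > lower && M[i, j] < upper) hits <- hits + 1
  }
  hits / total
}

# within-cluster consensus score by direct pair enumeration
cluster_consensus_oracle <- function(M, labels, c_idx) {
  members <- which(labels == c_idx)
  if (length(members) < 2) return(1)
  acc <- 0; cnt <- 0
  for (a in seq_along(members)) for (b in seq_along(members)) {
    if (a < b) { acc <- acc + M[members[a], members[b]]; cnt <- cnt + 1 }
  }
  acc / cnt
}

# hand product-limit computation (events precede censorings at ties)
km_oracle <- function(times, events) {
  ord <- order(times, -events)
  times <- times[ord]; events <- events[ord]
  s <- 1; out_t <- c(); out_s <- c()
  for (t in sort(unique(times[events == 1]))) {
    n_risk <- sum(times >= t)
    d <- sum(times == t & events == 1)
    s <- s * (1 - d / n_risk)
    out_t <- c(out_t, t); out_s <- c(out_s, s)
  }
  list(time = out_t, surv = out_s)
}

# textbook two-group log-rank statistic
logrank_oracle_2g <- function(t1, e1, t2, e2) {
  times <- c(t1, t2); events <- c(e1, e2)
  grp <- c(rep(1, length(t1)), rep(2, length(t2)))
  u <- 0; v <- 0
  for (t in sort(unique(times[events == 1]))) {
    n_t <- sum(times >= t)
    n1_t <- sum(times >= t & grp == 1)
    d_t <- sum(times == t & events == 1)
    d1_t <- sum(times == t & events == 1 & grp == 1)
    u <- u + d1_t - d_t * n1_t / n_t
    if (n_t > 1) {
      v <- v + d_t * (n1_t / n_t) * (1 - n1_t / n_t) * (n_t - d_t) / (n_t - 1)
    }
  }
  u^2 / v
}

# exhaustive optimal 2-medoid bipartition on a small dissimilarity matrix
best_bipartition_oracle <- function(d) {
  n <- nrow(d)
  best_cost <- Inf; best <- NULL
  for (code in 1:(2^(n - 1) - 1)) {
    side <- as.integer(intToBits(code))[1:n]
    if (all(side == 0) || all(side == 1)) next
    cost <- 0
    for (s in 0:1) {
      members <- which(side == s)
      cost <- cost + min(vapply(members, function(m) sum(d[members, m]), 0))
    }
    if (cost < best_cost) { best_cost <- cost; best <- side }
  }
  best + 1L
}

# two clean 1-d blobs -> distance matrix with known membership
blob_distance <- function(n_per = 10, gap = 1, seed = 1) {
  set.seed(seed)
  x <- c(rnorm(n_per, 0, 0.02), rnorm(n_per, gap, 0.02))
  structure(list(values = abs(outer(x, x, "-")),
                 subject_id = paste0("S", seq_along(x))),
            class = "distance_matrix")
}

# agreement of two partitions up to label permutation
same_partition <- function(a, b) {
  length(unique(paste(a, b))) == length(unique(a)) &&
    length(unique(a)) == length(unique(b))
}
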