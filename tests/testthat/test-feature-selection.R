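test_that("symmetrical uncertainty matches hand-computed contingencies", {
  # identical non-constant variables
  x <- c(1, 1, 2, 2, 1, 2)
  expect_equal(symmetrical_uncertainty(x, x), 1.0)
  # 2x2 joint counts (2,0,0,2): perfectly dependent
  expect_equal(symmetrical_uncertainty(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1.0)
  # joint counts (1,1,1,1): independent
  expect_equal(symmetrical_uncertainty(c(1, 1, 2, 2), c(1, 2, 1, 2)), 0.0)
  # constant column guard
  expect_equal(symmetrical_uncertainty(rep(1, 10), c(rep(1, 5), rep(2, 5))), 0)

  # large-sample independence: SU near 0
  withr::with_seed(1, {
    su <- symmetrical_uncertainty(rnorm(5000), rnorm(5000))
    expect_lt(su, 0.02)
  })
})

test_that("SU is symmetric, bounded, and agrees with an independent oracle", {
  withr::with_seed(3, {
    for (i in 1:20) {
      x <- sample(1:4, 60, replace = TRUE)
      y <- sample(1:3, 60, replace = TRUE)
      a <- symmetrical_uncertainty(x, y)
      expect_equal(a, symmetrical_uncertainty(y, x), tolerance = 1e-12)
      expect_gte(a, 0); expect_lte(a, 1)
      expect_equal(a, su_oracle(x, y), tolerance = 1e-12)
    }
  })
})

test_that("CFS selects the separating feature and drops duplicates and noise", {
  tab <- planted_table(sep = 3, noise_sd = 0.3, seed = 5)
  sel <- cfs_select(tab)
  expect_true("informative" %in% sel$names ||
                "duplicate" %in% sel$names)
  # exact redundancy: never both copies
  expect_false(all(c("informative", "duplicate") %in% sel$names))
  expect_false(any(grepl("^noise", sel$names)))

  const <- feature_table(data.frame(a = rep(1, 20), b = rep(2, 20)),
                         rep(c("faller", "non_faller"), 10))
  expect_error(cfs_select(const), "constant")
})

test_that("CFS best-first search attains the exhaustive-search merit", {
  # 6-feature table; oracle enumerates all non-empty subsets with an
  # independently coded merit
  withr::with_seed(11, {
    n <- 80
    y <- rep(c("faller", "non_faller"), c(30, 50))
    X <- data.frame(
      f1 = ifelse(y == "faller", 1.5, 0) + rnorm(n),
      f2 = ifelse(y == "faller", -1, 0) + rnorm(n),
      f3 = rnorm(n), f4 = rnorm(n), f5 = rnorm(n), f6 = rnorm(n)
    )
  })
  tab <- feature_table(X, y)
  sel <- cfs_select(tab)

  disc <- lapply(X, discretize_ef)
  ycode <- as.integer(factor(y))
  merit_oracle <- function(set) {
    k <- length(set)
    rcf <- mean(vapply(set, function(f) su_oracle(disc[[f]], ycode), numeric(1)))
    if (k == 1) return(rcf)
    prs <- utils::combn(set, 2)
    rff <- mean(apply(prs, 2, function(p) su_oracle(disc[[p[1]]], disc[[p[2]]])))
    k * rcf / sqrt(k + k * (k - 1) * rff)
  }
  all_subsets <- unlist(lapply(1:6, function(s)
    utils::combn(names(X), s, simplify = FALSE)), recursive = FALSE)
  best <- max(vapply(all_subsets, merit_oracle, numeric(1)))
  expect_equal(sel$merit, best, tolerance = 1e-9)
})

test_that("FCBF keeps one copy of duplicated features and honours delta", {
  tab <- planted_table(sep = 3, noise_sd = 0.3, seed = 7)
  sel <- fcbf_select(tab)
  expect_equal(sum(c("informative", "duplicate") %in% sel$names), 1)
  expect_error(fcbf_select(tab, delta = 1), "threshold")
})

test_that("FCBF reproduces a step-by-step hand trace of the predominance rule", {
  # Discrete 5-feature table, n = 16. With A = label exactly, SU(A, y) = 1;
  # B duplicates A; C agrees with the label on 12/16 rows; D is constant
  # within blocks unrelated to y; E is a fixed permutation pattern.
  y <- rep(c("faller", "non_faller"), each = 8)
  A <- rep(c(1, 2), each = 8)
  B <- A
  C <- c(1, 1, 1, 1, 1, 1, 2, 2, 2, 2, 2, 2, 1, 1, 1, 1)
  D <- rep(c(1, 2), 8)
  E <- c(1, 2, 1, 2, 2, 1, 2, 1, 1, 2, 1, 2, 2, 1, 2, 1)
  tab <- feature_table(data.frame(A = A, B = B, C = C, D = D, E = E), y)
  # hand trace: rank by SU(., y): A=1, B=1 (tie -> A first), C, then D=E=0
  # dropped by delta = 0. A retained; B removed (SU(B,A)=1 >= SU(B,y)=1);
  # C removed (SU(C,A) = SU(C,y) because A == y). Result: {A}.
  sel <- fcbf_select(tab)
  expect_identical(sel$names, "A")
})

test_that("Relief-F weight matches a manual update trace (n=6, k=1)", {
  x <- c(0, 0.1, 0.2, 0.8, 0.9, 1.0)
  y <- rep(c("faller", "non_faller"), each = 3)
  tab <- feature_table(data.frame(x = x), y)
  w <- relieff_rank(tab, k_neighbors = 1)
  # per-instance updates (hit diff, miss diff):
  # (0.1,0.8),(0.1,0.7),(0.1,0.6),(0.1,0.6),(0.1,0.7),(0.1,0.8)
  # weight = sum(miss - hit)/6 = (0.7+0.6+0.5+0.5+0.6+0.7)/6 = 0.6
  expect_equal(unname(w["x"]), 0.6, tolerance = 1e-12)
})

test_that("Relief-F ranks informative above noise and keeps duplicates equal", {
  tab <- planted_table(sep = 2, noise_sd = 0.5, seed = 9)
  w <- relieff_rank(tab, k_neighbors = 10)
  expect_equal(w[["informative"]], w[["duplicate"]], tolerance = 1e-12)
  expect_gt(w[["informative"]], max(w[grepl("^noise", names(w))]))
  expect_error(relieff_rank(tab, k_neighbors = 25), "k_neighbors")
})

test_that("Relief-F separates an injected effect from noise in >= 95% of runs", {
  hits <- 0
  for (seed in 1:100) {
    tab <- planted_table(n_faller = 15, n_nonfaller = 25, n_noise = 5,
                         sep = 2, noise_sd = 1, seed = seed)
    tab$features$duplicate <- NULL
    w <- relieff_rank(tab, k_neighbors = 5)
    if (w[["informative"]] > max(w[grepl("^noise", names(w))])) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("selection output is invariant to row permutation", {
  tab <- planted_table(seed = 13)
  perm <- withr::with_seed(1, sample(nrow(tab$features)))
  ptab <- feature_table(tab$features[perm, , drop = FALSE],
                        as.character(tab$labels)[perm])
  expect_identical(cfs_select(tab)$names, cfs_select(ptab)$names)
  expect_identical(fcbf_select(tab)$names, fcbf_select(ptab)$names)
  expect_equal(relieff_rank(tab, k_neighbors = 8),
               relieff_rank(ptab, k_neighbors = 8), tolerance = 1e-9)
})

test_that("the three methods disagree on redundancy exactly as documented", {
  tab <- planted_table(sep = 3, noise_sd = 0.3, seed = 15)
  cfs <- cfs_select(tab)$names
  fcbf <- fcbf_select(tab)$names
  w <- relieff_rank(tab, k_neighbors = 10)
  expect_lte(sum(c("informative", "duplicate") %in% cfs), 1)
  expect_lte(sum(c("informative", "duplicate") %in% fcbf), 1)
  expect_equal(w[["informative"]], w[["duplicate"]], tolerance = 1e-12)
})

test_that("subset sizing returns everything for small tables and scales up", {
  tab4 <- planted_table(n_noise = 2, seed = 17)   # 4 columns
  w4 <- relieff_rank(tab4, k_neighbors = 5)
  sel4 <- relieff_subset_size(tab4, w4)
  expect_setequal(sel4$names, names(tab4$features))

  # 10 informative + 40 noise: the top increment already suffices
  withr::with_seed(19, {
    n <- 100
    y <- rep(c("faller", "non_faller"), c(30, 70))
    X <- as.data.frame(matrix(rnorm(n * 40), n))
    names(X) <- sprintf("noise%02d", 1:40)
    for (j in 1:10) {
      X[[sprintf("inf%02d", j)]] <- ifelse(y == "faller", 1.2, 0) + rnorm(n, 0, 0.6)
    }
  })
  tab <- feature_table(X, y)
  w <- relieff_rank(tab, k_neighbors = 10)
  sel <- relieff_subset_size(tab, w, seed = 2)
  expect_lte(length(sel$names), 15)
})
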