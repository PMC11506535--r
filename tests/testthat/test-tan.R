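test_that("equal-frequency discretization places edges at straddling midpoints", {
  tab <- data.frame(x = 1:9, diagnosis = rep(0:1, length.out = 9) )
  # x is integer-valued with few states, so force binning via the cap
  d <- discretize(tab, n_bins = 3, max_discrete_states = 5)
  expect_identical(d$scheme$x$kind, "binned")
  expect_equal(d$scheme$x$edges, c(3.5, 6.5))
  expect_identical(as.integer(table(d$data$x)), c(3L, 3L, 3L))

  expect_error(discretize(tab, n_bins = 1), "n_bins")

  # binary variable kept as-is with 2 states
  tab2 <- data.frame(x = rep(0:1, 10), diagnosis = rep(0:1, 10))
  d2 <- discretize(tab2)
  expect_identical(d2$scheme$x$kind, "discrete")
  expect_identical(d2$scheme$x$n_states, 2L)

  # constant variable dropped with a warning
  tab3 <- data.frame(x = rep(1, 10), y = rnorm(10), diagnosis = rep(0:1, 5))
  expect_warning(d3 <- discretize(tab3), "constant")
  expect_false("x" %in% names(d3$data))

  # scheme application maps unseen values to sensible states
  sc <- d$scheme
  new <- apply_scheme(sc, data.frame(x = c(0, 5, 100)))
  expect_identical(new$x, c(1L, 2L, 3L))
})

test_that("deterministic feature copies are joined by a tree edge", {
  set.seed(31)
  n <- 400
  x1 <- sample(1:3, n, TRUE)
  tab <- data.frame(x1 = x1, x2 = x1,
                    x3 = sample(1:3, n, TRUE), x4 = sample(1:3, n, TRUE),
                    diagnosis = sample(0:1, n, TRUE))
  m <- tan_fit(tab, variant = "tan")
  pairs <- apply(m$tree_edges, 1, function(e) paste(sort(e), collapse = "-"))
  expect_true("x1-x2" %in% pairs)

  # exhaustive spanning-tree oracle: the learned tree attains the maximum
  # total conditional mutual information over all spanning trees
  vars <- m$nodes
  W <- matrix(0, 4, 4, dimnames = list(vars, vars))
  y <- tab$diagnosis
  for (i in 1:3) for (j in (i + 1):4)
    W[i, j] <- W[j, i] <- thermotan:::cmi_bits(tab[[vars[i]]], tab[[vars[j]]], y)
  all_edges <- t(combn(4, 2))
  best <- -Inf
  for (sel in combn(nrow(all_edges), 3, simplify = FALSE)) {
    es <- all_edges[sel, , drop = FALSE]
    g <- igraph::graph_from_edgelist(es, directed = FALSE)
    if (igraph::vcount(g) == 4 && igraph::is_connected(g))
      best <- max(best, sum(W[es]))
  }
  got <- sum(apply(m$tree_edges, 1, function(e) W[e[1], e[2]]))
  expect_equal(got, best, tolerance = 1e-12)
})

test_that("CPT rows are normalized and smoothing handles unseen states", {
  set.seed(4)
  tab <- data.frame(a = sample(1:3, 60, TRUE), b = sample(1:2, 60, TRUE),
                    diagnosis = sample(0:1, 60, TRUE))
  m <- tan_fit(tab, variant = "tan", alpha = 1)
  for (v in m$nodes) {
    cpt <- m$cpts[[v]]
    sums <- apply(cpt, seq_along(dim(cpt))[-1], sum)
    expect_equal(as.vector(sums), rep(1, length(sums)), tolerance = 1e-9)
  }
  expect_equal(sum(m$prior), 1, tolerance = 1e-12)
})

test_that("independent features produce a near-zero tree and TAN ~ NB", {
  set.seed(8)
  n <- 4000
  tab <- data.frame(a = sample(1:3, n, TRUE), b = sample(1:3, n, TRUE),
                    c = sample(1:3, n, TRUE),
                    diagnosis = sample(0:1, n, TRUE))
  m <- tan_fit(tab, variant = "tan")
  W <- vapply(seq_len(nrow(m$tree_edges)), function(i)
    thermotan:::cmi_bits(tab[[m$tree_edges[i, 1]]],
                         tab[[m$tree_edges[i, 2]]], tab$diagnosis),
    numeric(1))
  expect_lt(max(W), 0.005)   # bits; plug-in bias is O(df / 2N ln 2)
  nb <- tan_fit(tab, variant = "nb")
  p_tan <- predict(m, tab[1:50, ])[["1"]]
  p_nb <- predict(nb, tab[1:50, ])[["1"]]
  expect_lt(max(abs(p_tan - p_nb)), 0.1)
})

test_that("posterior matches hand calculation on a 2-feature binary model", {
  # deterministic two-feature table with known counts
  tab <- data.frame(
    a = c(1, 1, 1, 2, 2, 2, 1, 2, 2, 2, 1, 1),
    b = c(1, 2, 1, 2, 1, 2, 2, 1, 2, 2, 1, 2),
    diagnosis = c(0, 0, 0, 0, 0, 0, 1, 1, 1, 1, 1, 1))
  m <- tan_fit(tab, variant = "nb", alpha = 1)
  # hand-computed Bayes rule with Laplace-1 smoothing:
  # P(y) = 7/14 each; class 0: a=1 in 3/6 -> (3+1)/(6+2)=4/8, b=1 in 3/6 -> 4/8
  # class 1: a=1 in 3/6 -> 4/8, b=1 in 2/6 -> 3/8
  p0 <- (7 / 14) * (4 / 8) * (4 / 8)
  p1 <- (7 / 14) * (4 / 8) * (3 / 8)
  post <- posterior(m, list(a = 1, b = 1))
  expect_equal(unname(post[["0"]]), p0 / (p0 + p1), tolerance = 1e-12)

  # no evidence returns the smoothed prior
  expect_equal(posterior(m, list()), m$prior, tolerance = 1e-15)
})

test_that("posterior equals the exhaustive-joint oracle on small models", {
  set.seed(12)
  for (trial in 1:6) {
    nf <- sample(2:6, 1)
    n <- 150
    tab <- as.data.frame(lapply(seq_len(nf), function(i) sample(1:3, n, TRUE)))
    names(tab) <- paste0("v", seq_len(nf))
    tab$diagnosis <- sample(0:1, n, TRUE)
    m <- tan_fit(tab, variant = sample(c("tan", "nb"), 1))
    # full, partial, and empty evidence
    for (n_ev in c(nf, sample(0:(nf - 1), 1))) {
      ev_vars <- sample(m$nodes, n_ev)
      ev <- stats::setNames(lapply(ev_vars, function(v) sample(1:3, 1)),
                            ev_vars)
      expect_equal(unname(posterior(m, ev)),
                   unname(posterior_oracle(m, ev)), tolerance = 1e-12)
    }
  }
})

test_that("TAN beats NB in test log-likelihood on TAN-generated data", {
  wins <- 0
  for (s in 1:20) {
    truth <- make_true_tan(n_feat = 4, k = 3, seed = s)
    train <- simulate(truth, nsim = 300, seed = 1000 + s)
    test <- simulate(truth, nsim = 200, seed = 2000 + s)
    m_tan <- tan_fit(train, variant = "tan")
    m_nb <- tan_fit(train, variant = "nb")
    if (tan_loglik(m_tan, test) >= tan_loglik(m_nb, test)) wins <- wins + 1
  }
  expect_gt(wins, 10)   # 20-seed majority
})

test_that("model methods print, summarize, simulate and serialize", {
  set.seed(9)
  tab <- data.frame(a = sample(1:3, 40, TRUE), b = sample(1:3, 40, TRUE),
                    diagnosis = rep(0:1, 20))
  m <- tan_fit(tab)
  expect_output(print(m), "TAN model")
  rep <- expect_output(summary(m), "mutual_information")
  sim <- simulate(m, nsim = 25, seed = 3)
  expect_identical(nrow(sim), 25L)
  expect_true(all(sim$a %in% 1:3))
  expect_true(all(sim$diagnosis %in% 0:1))
  ll <- logLik(m)
  expect_lt(as.numeric(ll), 0)
  path <- withr::local_tempfile(fileext = ".json")
  write_tan_model(m, path)
  obj <- jsonlite::read_json(path)
  expect_identical(obj$target, "diagnosis")
  expect_setequal(unlist(obj$nodes), c("a", "b"))
})

test_that("the MI report reproduces its analytic identities", {
  y <- rep(0:1, c(211, 153))
  tab <- data.frame(copy = y, diagnosis = y)
  rep <- mi_report(tab, "diagnosis")
  h <- thermotan:::entropy_bits(y)
  expect_equal(rep$mutual_information[1], h, tolerance = 1e-12)
  expect_equal(rep$relative_mi[1], 100, tolerance = 1e-9)
  expect_equal(rep$normalized_mi[1], 100 * h, tolerance = 1e-9)
  expect_equal(rep$g_test[1], 2 * 364 * log(2) * h, tolerance = 1e-9)
  expect_equal(rep$relative_significance[1], 1)

  # permutation null: mean MI stays near the chi-square-implied bias level
  set.seed(6)
  x3 <- sample(1:3, 364, TRUE)
  mis <- replicate(100, mutual_information(sample(x3), y))
  expect_lt(mean(mis), 3 / (2 * 364 * log(2)))   # mean chi2 = df = 2
  ps <- vapply(1:100, function(i) {
    g <- 2 * 364 * log(2) * mutual_information(sample(x3), y)
    stats::pchisq(g, 2, lower.tail = FALSE)
  }, numeric(1))
  expect_gt(mean(ps), 0.35); expect_lt(mean(ps), 0.65)
})
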