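# shared fixtures; heavy objects are built once per test run and cached

.fixtures <- new.env(parent = emptyenv())

random_grid <- function(h = 6, w = 7, lo = 26, hi = 38, p_mask = 0.15) {
  v <- matrix(stats::runif(h * w, lo, hi), h, w)
  m <- matrix(stats::runif(h * w) > p_mask, h, w)
  if (!any(m)) m[1, 1] <- TRUE
  thermogram(v, mask = m)
}

easy_spec <- function(n_healthy = 40, n_sick = 30, seed = 5) {
  cohort_spec(n_healthy = n_healthy, n_sick = n_sick,
              grid_height = 24, grid_width = 24,
              hotspot_delta_range = c(2.5, 4), noise_sd = 0.2, seed = seed)
}

# native composite aspect (two 24x24 breasts side by side): no horizontal
# compression, so explanation masks map back to grid cells one-to-one
small_cnn_config <- function(seed = 11, ...) {
  cnn_config(input_size = c(24, 48, 1), seed = seed, ...)
}

# easy cohort with composite segmented grids and preprocessed images
easy_cohort <- function() {
  if (is.null(.fixtures$easy)) {
    co <- generate_cohort(easy_spec())
    cfg <- small_cnn_config()
    comps <- lapply(co$pairs, function(p)
      threshold_segment(thermotan:::combine_pair(p), 29))
    imgs <- lapply(comps, preprocess_for_cnn, config = cfg)
    .fixtures$easy <- list(cohort = co, composites = comps, images = imgs,
                           y = co$records$diagnosis, cfg = cfg)
  }
  .fixtures$easy
}

# one CNN trained on the full easy cohort (used by explainer tests)
easy_cnn <- function() {
  if (is.null(.fixtures$cnn)) {
    e <- easy_cohort()
    .fixtures$cnn <- cnn_train(cnn_build(e$cfg), e$images, e$y)
  }
  .fixtures$cnn
}

quick_run_config <- function(seed = 7, ...) {
  run_config(cohort = easy_spec(seed = 1),  # seed re-derived from run seed
             cnn = small_cnn_config(), K = 5, seed = seed, ...)
}

# naive reference implementation of the factor panel, independent of
# extract_factors: plain loops and direct formulas
reference_factors <- function(aff_values, aff_mask, h_values, h_mask) {
  va <- c(); coords <- list()
  for (i in seq_len(nrow(aff_values))) for (j in seq_len(ncol(aff_values)))
    if (aff_mask[i, j]) {
      va <- c(va, aff_values[i, j]); coords[[length(coords) + 1]] <- c(i, j)
    }
  vh <- h_values[h_mask]
  tmax <- max(va); tmin <- min(va); mu <- sum(va) / length(va)
  # first max / min in row-major order
  first_at <- function(val) {
    for (i in seq_len(nrow(aff_values))) for (j in seq_len(ncol(aff_values)))
      if (aff_mask[i, j] && aff_values[i, j] == val) return(c(i, j))
  }
  pmx <- first_at(tmax); pmn <- first_at(tmin)
  svals <- sort(va); n <- length(va)
  med <- if (n %% 2 == 1) svals[(n + 1) / 2] else
    (svals[n / 2] + svals[n / 2 + 1]) / 2
  variance <- sum((va - mu)^2) / n
  theta <- mu + 0.5 * (tmax - mu)
  above <- aff_mask & !is.na(aff_values) & aff_values > theta
  above[!aff_mask] <- FALSE
  C <- sum(above)
  # flood fill, 8-connected
  A <- 0
  if (above[pmx[1], pmx[2]]) {
    todo <- list(pmx); inset <- matrix(FALSE, nrow(above), ncol(above))
    inset[pmx[1], pmx[2]] <- TRUE
    while (length(todo)) {
      cu <- todo[[1]]; todo <- todo[-1]
      for (di in -1:1) for (dj in -1:1) {
        i <- cu[1] + di; j <- cu[2] + dj
        if ((di || dj) && i >= 1 && j >= 1 && i <= nrow(above) &&
            j <= ncol(above) && above[i, j] && !inset[i, j]) {
          inset[i, j] <- TRUE; todo[[length(todo) + 1]] <- c(i, j)
        }
      }
    }
    A <- sum(inset)
  }
  muh <- sum(vh) / length(vh)
  c(Max_Temperature = tmax, Min_temperature = tmin,
    Temperature_Range = tmax - tmin, Mean = mu, Median = med,
    Standard_Deviation = sqrt(variance), Variance = variance,
    Deviation_From_Mean = tmax - mu, MaxMax = tmax - max(vh),
    MaxMin = tmax - min(vh), Deviation_Mean_Healthy = tmax - muh,
    Mean_Difference = mu - muh,
    D = sqrt((pmx[1] - pmn[1])^2 + (pmx[2] - pmn[2])^2),
    A = A, B = n, C = C, `A/B` = A / n, `C/B` = C / n)
}

# hand-constructed ground-truth TAN model over a feature chain, for
# simulation-based recovery tests
make_true_tan <- function(n_feat = 4, k = 3, seed = 1, strength = 6) {
  set.seed(seed)
  nodes <- paste0("f", seq_len(n_feat))
  parent <- stats::setNames(c(NA_character_, nodes[-n_feat]), nodes)
  rdir <- function(k, conc) { g <- stats::rgamma(k, conc); g / sum(g) }
  cpts <- list()
  for (v in seq_len(n_feat)) {
    if (v == 1) {
      a <- array(0, c(k, 2))
      for (y in 1:2) a[, y] <- rdir(k, 0.5)
    } else {
      a <- array(0, c(k, 2, k))
      for (y in 1:2) for (p in 1:k) {
        w <- rep(1, k); w[p] <- strength     # strong dependence on parent
        g <- stats::rgamma(k, w); a[, y, p] <- g / sum(g)
      }
    }
    cpts[[nodes[v]]] <- a
  }
  structure(list(target = "diagnosis", nodes = nodes,
                 tree_edges = cbind(parent = nodes[-n_feat],
                                    child = nodes[-1]),
                 parent = parent, cpts = cpts,
                 prior = stats::setNames(c(0.55, 0.45), c("0", "1")),
                 levels = c(stats::setNames(rep(list(seq_len(k)), n_feat),
                                            nodes),
                            list(diagnosis = c(0L, 1L))),
                 n_states = stats::setNames(rep(k, n_feat), nodes),
                 alpha = 1, variant = "tan", scheme = NULL, n_obs = 0,
                 train_data = NULL),
            class = "tan_model")
}

# exhaustive-joint posterior oracle for small discrete models
posterior_oracle <- function(model, evidence) {
  ky <- length(model$prior)
  ks <- model$n_states[model$nodes]
  grid <- do.call(expand.grid, lapply(ks, seq_len))
  names(grid) <- model$nodes
  for (v in names(evidence))
    grid <- grid[grid[[v]] == match(evidence[[v]], model$levels[[v]]), ,
                 drop = FALSE]
  num <- vapply(seq_len(ky), function(yi) {
    tot <- 0
    for (r in seq_len(nrow(grid))) {
      p <- model$prior[yi]
      for (v in model$nodes) {
        s <- grid[r, v]
        p <- p * if (is.na(model$parent[[v]])) model$cpts[[v]][s, yi]
        else model$cpts[[v]][s, yi, grid[r, model$parent[[v]]]]
      }
      tot <- tot + p
    }
    tot
  }, numeric(1))
  num / sum(num)
}
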