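# ---- discretization --------------------------------------------------------

#' Discretize a factor table for the Bayesian network
#'
#' Continuous variables are binned into `n_bins` states (default 3) with
#' edges placed from the supplied data only — in equal-frequency mode each
#' cut sits at the midpoint between the two order statistics straddling the
#' quantile boundary. Integer-valued variables with at most
#' `max_discrete_states` distinct values (ages, pixel counts, binary flags)
#' are kept discrete as-is. Constant variables are dropped with a warning.
#'
#' @param table data.frame; non-numeric columns and `patient_id` are left
#'   untouched, the `target` column is kept as-is.
#' @param target name of the class column.
#' @param n_bins number of states for binned variables, >= 2.
#' @param method `"equal_frequency"` or `"equal_width"`.
#' @param max_discrete_states integer-valued variables with more distinct
#'   values than this are binned like continuous ones.
#' @return A list with `data` (discretized data.frame: integer states
#'   `1..n_states` per modeled variable) and `scheme` (per-variable kind,
#'   bin edges or state values, and state count) reusable on new data via
#'   [apply_scheme()].
#' @export
discretize <- function(table, target = "diagnosis", n_bins = 3L,
                       method = c("equal_frequency", "equal_width"),
                       max_discrete_states = 80L) {
  method <- match.arg(method)
  if (n_bins < 2L) stop("'n_bins' must be >= 2", call. = FALSE)
  scheme <- list()
  out <- table
  drop <- character()
  for (nm in setdiff(names(table), c(target, "patient_id"))) {
    x <- table[[nm]]
    if (!is.numeric(x)) next
    ux <- sort(unique(x))
    if (length(ux) < 2L) {
      warning(sprintf("variable '%s' is constant; dropped from modeling", nm),
              call. = FALSE)
      drop <- c(drop, nm)
      next
    }
    integerish <- all(abs(x - round(x)) < 1e-9)
    if (integerish && length(ux) <= max_discrete_states) {
      scheme[[nm]] <- list(kind = "discrete", states = ux,
                           n_states = length(ux))
      out[[nm]] <- match(x, ux)
      next
    }
    if (length(ux) < n_bins) {
      scheme[[nm]] <- list(kind = "discrete", states = ux,
                           n_states = length(ux))
      out[[nm]] <- match(x, ux)
      next
    }
    if (method == "equal_frequency") {
      xs <- sort(x)
      n <- length(xs)
      cuts <- vapply(seq_len(n_bins - 1L), function(b) {
        i <- round(b * n / n_bins)
        (xs[i] + xs[i + 1L]) / 2
      }, numeric(1))
    } else {
      cuts <- min(x) + diff(range(x)) * seq_len(n_bins - 1L) / n_bins
    }
    cuts <- unique(cuts)
    if (!length(cuts)) {
      warning(sprintf("variable '%s' cannot be split; dropped from modeling", nm),
              call. = FALSE)
      drop <- c(drop, nm)
      next
    }
    scheme[[nm]] <- list(kind = "binned", edges = cuts,
                         n_states = length(cuts) + 1L)
    out[[nm]] <- findInterval(x, cuts) + 1L
  }
  out <- out[, setdiff(names(out), drop), drop = FALSE]
  structure(list(data = out, scheme = scheme), class = "discretization")
}

#' Apply a discretization scheme to new data
#'
#' Binned variables are cut at the stored edges; discrete-as-is variables
#' are mapped to the nearest stored state (ties to the lower state), so
#' previously unseen values never produce missing states.
#'
#' @param scheme the `scheme` element of a [discretize()] result.
#' @param table data.frame of raw values.
#' @return The data.frame with modeled columns replaced by integer states.
#' @export
apply_scheme <- function(scheme, table) {
  for (nm in names(scheme)) {
    if (!nm %in% names(table)) next
    s <- scheme[[nm]]
    x <- table[[nm]]
    if (s$kind == "binned") {
      table[[nm]] <- findInterval(x, s$edges) + 1L
    } else {
      table[[nm]] <- vapply(x, function(v) {
        d <- abs(s$states - v)
        which(d == min(d))[1L]
      }, integer(1))
    }
  }
  table
}

# ---- information measures --------------------------------------------------

#' Mutual information of two discrete variables, in bits
#'
#' Maximum-likelihood plug-in estimate (no bias correction), the estimator
#' for which the G-test identity `G = 2 N ln(2) MI` holds exactly.
#'
#' @param x,y equal-length vectors of discrete values.
#' @return MI in bits.
#' @export
mutual_information <- function(x, y) {
  t <- table(x, y)
  n <- sum(t)
  p <- t / n
  px <- rowSums(p); py <- colSums(p)
  e <- outer(px, py)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / e[nz]))
}

entropy_bits <- function(x) {
  p <- table(x) / length(x)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# conditional mutual information I(x; y | z), bits, plug-in
cmi_bits <- function(x, y, z) {
  n <- length(z)
  out <- 0
  for (zv in unique(z)) {
    sel <- z == zv
    out <- out + sum(sel) / n * mutual_information(x[sel], y[sel])
  }
  out
}

# ---- TAN / NB fitting ------------------------------------------------------

encode_column <- function(x) {
  lv <- sort(unique(x))
  list(states = match(x, lv), levels = lv)
}

max_spanning_tree <- function(vars, weights) {
  # weights: named list/matrix lookup by pair; Kruskal with deterministic
  # lexicographic tie-break on the sorted variable-name pair
  pairs <- t(utils::combn(sort(vars), 2))
  w <- apply(pairs, 1, function(p) weights[p[1], p[2]])
  ord <- order(-w, pairs[, 1], pairs[, 2])
  parent <- stats::setNames(vars, vars)
  find <- function(v) { while (parent[[v]] != v) v <- parent[[v]]; v }
  edges <- list()
  for (i in ord) {
    a <- pairs[i, 1]; b <- pairs[i, 2]
    ra <- find(a); rb <- find(b)
    if (ra != rb) {
      parent[[ra]] <- rb
      edges[[length(edges) + 1L]] <- c(a, b)
    }
    if (length(edges) == length(vars) - 1L) break
  }
  do.call(rbind, edges)
}

orient_tree <- function(vars, edges, root) {
  # breadth-first orientation outward from root; returns named parent vector
  adj <- stats::setNames(vector("list", length(vars)), vars)
  if (!is.null(edges)) {
    for (i in seq_len(nrow(edges))) {
      a <- edges[i, 1]; b <- edges[i, 2]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  par <- stats::setNames(rep(NA_character_, length(vars)), vars)
  visited <- stats::setNames(rep(FALSE, length(vars)), vars)
  queue <- root
  visited[root] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (u in adj[[v]]) if (!visited[u]) {
      visited[u] <- TRUE
      par[u] <- v
      queue <- c(queue, u)
    }
  }
  par
}

#' Fit a (tree-augmented) naive Bayes diagnostic network
#'
#' The class variable is parent of every feature. The `"nb"` variant stops
#' there; the `"tan"` variant additionally learns a tree over the features:
#' pairwise class-conditional mutual information `I(Xi; Xj | Y)` (bits,
#' maximum-likelihood plug-in) weights a maximum-weight spanning tree
#' (Kruskal, ties broken by the lexicographic variable-name pair), which is
#' oriented outward from the alphabetically first feature, so every feature
#' gains at most one feature parent. Conditional probability tables use
#' Laplace smoothing with pseudo-count `alpha`.
#'
#' The root choice does not change the distribution the model represents;
#' it is fixed alphabetically for determinism only.
#'
#' @param data data.frame of discrete features plus the `target` column
#'   (e.g. the `data` element of [discretize()]).
#' @param target name of the class column (binary or small-arity).
#' @param variant `"tan"` or `"nb"`.
#' @param alpha Laplace smoothing pseudo-count (default 1).
#' @param scheme optional discretization scheme stored alongside the model;
#'   when present, [predict.tan_model()] accepts raw continuous tables.
#' @return An object of class `"tan_model"`: `target`, `nodes`,
#'   `tree_edges` (2-column matrix `parent -> child`, `NULL` for nb),
#'   `parent` (named vector), `cpts`, `prior`, `levels`, `alpha`,
#'   `variant`, `scheme`.
#' @examples
#' d <- data.frame(x = rep(1:2, 8), y = rep(1:2, each = 8),
#'                 diagnosis = rep(0:1, each = 8))
#' m <- tan_fit(d, variant = "nb")
#' predict(m, d[1:2, ])
#' @export
tan_fit <- function(data, target = "diagnosis", variant = c("tan", "nb"),
                    alpha = 1, scheme = NULL) {
  variant <- match.arg(variant)
  stopifnot(is.data.frame(data), target %in% names(data))
  data <- data[, setdiff(names(data), "patient_id"), drop = FALSE]
  vars <- setdiff(names(data), target)
  if (!length(vars)) stop("no feature columns", call. = FALSE)
  # variables backed by a discretization scheme keep their full state space
  # (states unseen in this training split stay as valid, smoothed states);
  # other variables are encoded over their observed sorted values
  enc <- lapply(vars, function(v) {
    if (!is.null(scheme) && v %in% names(scheme)) {
      k <- scheme[[v]]$n_states
      list(states = as.integer(data[[v]]), levels = seq_len(k))
    } else encode_column(data[[v]])
  })
  names(enc) <- vars
  y_enc <- encode_column(data[[target]])
  enc[[target]] <- y_enc
  if (length(y_enc$levels) < 2L)
    stop("target must have at least 2 observed classes", call. = FALSE)
  if (min(table(y_enc$states)) < 2L)
    stop("need at least 2 rows per class", call. = FALSE)
  X <- lapply(enc[vars], `[[`, "states")
  y <- y_enc$states
  ky <- length(y_enc$levels)
  n_states <- vapply(vars, function(v) length(enc[[v]]$levels), integer(1))
  names(n_states) <- vars

  tree_edges <- NULL
  par <- stats::setNames(rep(NA_character_, length(vars)), vars)
  if (variant == "tan" && length(vars) >= 2L) {
    W <- matrix(0, length(vars), length(vars),
                dimnames = list(vars, vars))
    for (i in seq_along(vars)) for (j in seq_along(vars)) if (i < j)
      W[vars[i], vars[j]] <- W[vars[j], vars[i]] <-
        cmi_bits(X[[vars[i]]], X[[vars[j]]], y)
    und <- max_spanning_tree(vars, W)
    root <- sort(vars)[1]
    par <- orient_tree(vars, und, root)
    ch <- !is.na(par)
    if (any(ch))
      tree_edges <- cbind(parent = unname(par[ch]), child = names(par)[ch])
  }

  N <- length(y)
  prior <- (tabulate(y, ky) + alpha) / (N + alpha * ky)
  names(prior) <- as.character(y_enc$levels)

  cpts <- list()
  for (v in vars) {
    kx <- n_states[[v]]
    if (is.na(par[[v]])) {
      cnt <- array(0, c(kx, ky))
      for (r in seq_len(N)) cnt[X[[v]][r], y[r]] <- cnt[X[[v]][r], y[r]] + 1
      tot <- rep(colSums(cnt), each = kx)
      cpt <- (cnt + alpha) / array(tot + alpha * kx, dim(cnt))
    } else {
      kp <- n_states[[par[[v]]]]
      cnt <- array(0, c(kx, ky, kp))
      Xp <- X[[par[[v]]]]
      for (r in seq_len(N))
        cnt[X[[v]][r], y[r], Xp[r]] <- cnt[X[[v]][r], y[r], Xp[r]] + 1
      tot <- apply(cnt, c(2, 3), sum)
      cpt <- (cnt + alpha) /
        array(rep(tot, each = kx) + alpha * kx, dim(cnt))
    }
    cpts[[v]] <- cpt
  }

  structure(list(target = target, nodes = vars, tree_edges = tree_edges,
                 parent = par, cpts = cpts, prior = prior,
                 levels = lapply(enc, `[[`, "levels"),
                 n_states = n_states, alpha = alpha, variant = variant,
                 scheme = scheme, n_obs = N,
                 train_data = data),
            class = "tan_model")
}

#' @export
print.tan_model <- function(x, ...) {
  cat(sprintf("<%s model: target '%s', %d features, fitted on %d rows, alpha = %g>\n",
              toupper(x$variant), x$target, length(x$nodes), x$n_obs, x$alpha))
  if (!is.null(x$tree_edges)) {
    cat("  feature tree:\n")
    apply(x$tree_edges, 1, function(e)
      cat(sprintf("    %s -> %s\n", e[1], e[2])))
  }
  invisible(x)
}

# map raw evidence values onto internal state indices
encode_evidence <- function(model, evidence) {
  ev <- list()
  for (v in intersect(names(evidence), model$nodes)) {
    val <- evidence[[v]]
    if (is.na(val)) next
    lv <- model$levels[[v]]
    s <- match(val, lv)
    if (is.na(s)) {
      # tolerate states defined by the scheme but absent from training
      if (is.numeric(val) && val >= 1 && val <= model$n_states[[v]])
        s <- as.integer(val)
      else next
    }
    ev[[v]] <- s
  }
  ev
}

#' Posterior class distribution given (partial) evidence
#'
#' Exact inference in the class-rooted tree: for each class state the
#' unobserved features are marginalized by sum-product message passing over
#' the feature tree (parent-first), which is linear in the number of
#' features; the class posterior is then normalized. With full evidence
#' this reduces to reading the factorized joint.
#'
#' @param model a [tan_fit()] model.
#' @param evidence named list/vector of observed feature values (raw level
#'   values; any subset of features, possibly empty).
#' @return Named numeric vector of posterior probabilities, one per class
#'   state, summing to 1. With empty evidence this is the smoothed class
#'   prior.
#' @export
posterior <- function(model, evidence = list()) {
  stopifnot(inherits(model, "tan_model"))
  ev <- encode_evidence(model, as.list(evidence))
  children <- split(names(model$parent)[!is.na(model$parent)],
                    model$parent[!is.na(model$parent)])
  roots <- model$nodes[is.na(model$parent[model$nodes])]
  ky <- length(model$prior)
  msg <- function(node, yi, parent_state) {
    cpt <- model$cpts[[node]]
    states <- if (!is.null(ev[[node]])) ev[[node]] else seq_len(model$n_states[[node]])
    kids <- children[[node]]
    total <- 0
    for (s in states) {
      p <- if (is.na(model$parent[[node]])) cpt[s, yi] else cpt[s, yi, parent_state]
      if (!is.null(kids))
        for (k in kids) p <- p * msg(k, yi, s)
      total <- total + p
    }
    total
  }
  post <- vapply(seq_len(ky), function(yi) {
    p <- model$prior[yi]
    for (r in roots) p <- p * msg(r, yi, NULL)
    p
  }, numeric(1))
  names(post) <- names(model$prior)
  post / sum(post)
}

#' Predict method for TAN models
#'
#' @param object a [tan_fit()] model.
#' @param newdata data.frame of features; if the model carries a
#'   discretization scheme, raw continuous values are discretized first.
#' @param type `"prob"` for class-posterior columns, `"class"` for the MAP
#'   class label.
#' @param ... unused.
#' @return data.frame of posterior probabilities (one column per class
#'   level) or a vector of class labels.
#' @export
predict.tan_model <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  if (!is.null(object$scheme)) newdata <- apply_scheme(object$scheme, newdata)
  probs <- t(vapply(seq_len(nrow(newdata)), function(r) {
    posterior(object, as.list(newdata[r, intersect(names(newdata),
                                                   object$nodes),
                                      drop = FALSE]))
  }, numeric(length(object$prior))))
  colnames(probs) <- names(object$prior)
  if (type == "class") {
    lv <- object$levels[[object$target]]
    return(lv[max.col(probs, ties.method = "last")])
  }
  as.data.frame(probs, check.names = FALSE)
}

#' Joint log-likelihood of a discrete table under a TAN model
#'
#' @param model a [tan_fit()] model.
#' @param data data.frame containing the target and feature columns, on the
#'   same discrete scale the model was fitted on.
#' @return Total log-likelihood (natural log) of `sum log P(y, x)`.
#' @export
tan_loglik <- function(model, data) {
  stopifnot(inherits(model, "tan_model"))
  ll <- 0
  for (r in seq_len(nrow(data))) {
    row <- data[r, , drop = FALSE]
    yi <- match(row[[model$target]], model$levels[[model$target]])
    p <- model$prior[yi]
    for (v in model$nodes) {
      s <- match(row[[v]], model$levels[[v]])
      if (is.na(s)) s <- as.integer(row[[v]])
      p <- p * if (is.na(model$parent[[v]])) model$cpts[[v]][s, yi]
      else model$cpts[[v]][s, yi, match(row[[model$parent[[v]]]],
                                        model$levels[[model$parent[[v]]]])]
    }
    ll <- ll + log(p)
  }
  ll
}

#' @export
logLik.tan_model <- function(object, ...) {
  ll <- tan_loglik(object, object$train_data)
  attr(ll, "df") <- NA
  attr(ll, "nobs") <- object$n_obs
  class(ll) <- "logLik"
  ll
}

#' Simulate records from a fitted TAN model
#'
#' Ancestral sampling: the class is drawn from the smoothed prior, then
#' features are drawn parent-first down the feature tree from their CPTs.
#'
#' @param object a [tan_fit()] model.
#' @param nsim number of rows.
#' @param seed integer seed.
#' @param ... unused.
#' @return data.frame on the model's discrete scale (original level
#'   values), including the target column.
#' @export
simulate.tan_model <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  ky <- length(object$prior)
  # parent-first variable order
  order_vars <- character()
  remaining <- object$nodes
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(v)
      is.na(object$parent[[v]]) || object$parent[[v]] %in% order_vars,
      logical(1))]
    order_vars <- c(order_vars, ready)
    remaining <- setdiff(remaining, ready)
  }
  out <- vector("list", nsim)
  for (r in seq_len(nsim)) {
    yi <- sample.int(ky, 1, prob = object$prior)
    row <- stats::setNames(vector("list", length(object$nodes)), object$nodes)
    for (v in order_vars) {
      cpt <- object$cpts[[v]]
      p <- if (is.na(object$parent[[v]])) cpt[, yi]
      else cpt[, yi, row[[object$parent[[v]]]]]
      row[[v]] <- sample.int(length(p), 1, prob = p)
    }
    out[[r]] <- c(row, stats::setNames(list(yi), ".y"))
  }
  df <- as.data.frame(do.call(rbind, lapply(out, function(r)
    unlist(r))), check.names = FALSE)
  # decode to original level values
  for (v in object$nodes) {
    lv <- object$levels[[v]]
    idx <- pmin(df[[v]], length(lv))
    df[[v]] <- lv[idx]
  }
  df[[object$target]] <- object$levels[[object$target]][df[[".y"]]]
  df[[".y"]] <- NULL
  df
}

# ---- mutual-information report --------------------------------------------

#' Node-by-node mutual information report
#'
#' Ranks every feature by its plug-in mutual information with the target,
#' in the style of BayesiaLab's "influence on target" table: MI (bits),
#' normalized MI (`MI / log2(k_target)`, percent), relative MI
#' (`MI / H(target)`, percent), relative significance (`MI / max MI`),
#' G-test statistic (`2 N ln(2) MI`, an algebraic identity of the plug-in
#' estimator), degrees of freedom `(r - 1)(c - 1)` over observed states,
#' and the upper-tail chi-square p-value. When `raw` is supplied, each
#' variable's prior mean on the undiscretized scale is reported as well.
#'
#' @param data discrete data.frame including the target column.
#' @param target name of the class column.
#' @param raw optional data.frame of the same rows on the original
#'   continuous scale, for the `prior_mean` column.
#' @return data.frame of class `"mi_report"`, sorted by MI descending.
#' @export
mi_report <- function(data, target = "diagnosis", raw = NULL) {
  vars <- setdiff(names(data), c(target, "patient_id"))
  y <- data[[target]]
  N <- length(y)
  hy <- entropy_bits(y)
  ky <- length(unique(y))
  rows <- lapply(vars, function(v) {
    x <- data[[v]]
    mi <- mutual_information(x, y)
    g <- 2 * N * log(2) * mi
    df <- (length(unique(x)) - 1L) * (length(unique(y)) - 1L)
    data.frame(node = v,
               mutual_information = mi,
               normalized_mi = 100 * mi / log2(ky),
               relative_mi = 100 * mi / hy,
               relative_significance = NA_real_,
               prior_mean = if (!is.null(raw) && v %in% names(raw) &&
                                is.numeric(raw[[v]])) mean(raw[[v]]) else NA_real_,
               g_test = g, df = df,
               p_value = stats::pchisq(g, df, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, rows)
  rep <- rep[order(-rep$mutual_information, rep$node), ]
  rep$relative_significance <- rep$mutual_information /
    max(rep$mutual_information)
  rownames(rep) <- NULL
  class(rep) <- c("mi_report", "data.frame")
  rep
}

#' @export
print.mi_report <- function(x, ...) {
  y <- x
  class(y) <- "data.frame"
  y$mutual_information <- sprintf("%.4f", y$mutual_information)
  for (nm in c("normalized_mi", "relative_mi"))
    y[[nm]] <- sprintf("%.4f%%", x[[nm]])
  y$relative_significance <- sprintf("%.4f", x$relative_significance)
  y$g_test <- sprintf("%.4f", x$g_test)
  y$p_value <- sprintf("%.4f%%", 100 * x$p_value)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Summary of a TAN model: structure and node influence
#'
#' @param object a [tan_fit()] model.
#' @param ... unused.
#' @return The [mi_report()] of the training data, invisibly; printed
#'   together with the model structure.
#' @export
summary.tan_model <- function(object, ...) {
  print(object)
  rep <- mi_report(object$train_data, object$target)
  print(rep)
  invisible(rep)
}

#' Serialize a TAN model to JSON
#'
#' @param model a [tan_fit()] model.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tan_model <- function(model, path) {
  obj <- list(target = model$target, nodes = model$nodes,
              variant = model$variant, alpha = model$alpha,
              tree_edges = model$tree_edges,
              prior = as.list(model$prior),
              levels = model$levels,
              n_states = as.list(model$n_states),
              cpts = lapply(model$cpts, function(a)
                list(dim = dim(a), values = as.vector(a))),
              scheme = model$scheme)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
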