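# 8-connected component of above-threshold cells containing a given cell;
# hand-rolled BFS because the available labeling routines are 4-connected
component8 <- function(member, start) {
  h <- nrow(member); w <- ncol(member)
  seen <- matrix(FALSE, h, w)
  if (!member[start[1], start[2]]) return(seen)
  queue <- matrix(start, ncol = 2)
  seen[start[1], start[2]] <- TRUE
  while (nrow(queue)) {
    cur <- queue[1, , drop = FALSE]
    queue <- queue[-1, , drop = FALSE]
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      i <- cur[1] + di; j <- cur[2] + dj
      if (i >= 1 && i <= h && j >= 1 && j <= w && member[i, j] && !seen[i, j]) {
        seen[i, j] <- TRUE
        queue <- rbind(queue, c(i, j))
      }
    }
  }
  seen
}

factor_names <- c("Max_Temperature", "Min_temperature", "Temperature_Range",
                  "Mean", "Median", "Standard_Deviation", "Variance",
                  "Deviation_From_Mean", "MaxMax", "MaxMin",
                  "Deviation_Mean_Healthy", "Mean_Difference",
                  "D", "A", "B", "C", "A/B", "C/B")

#' Thermal asymmetry factors of an affected/healthy breast pair
#'
#' Computes the panel of statistical factors that feed the diagnostic
#' network, from the valid cells of the two ROIs. On the affected ROI:
#' maximum, minimum, range, mean, median, population standard deviation and
#' variance, the deviation of the maximum from the mean, the distance `D`
#' (Euclidean, in pixels) between the maximum- and minimum-temperature
#' cells, and the hot-area counts `A`, `B`, `C` for the threshold
#' `theta = mean + 0.5 * (max - mean)`: `C` counts all valid cells strictly
#' above `theta`, `B` all valid cells, and `A` the cells of the 8-connected
#' above-`theta` component containing the maximum cell ("near the
#' maximum"), so `A <= C <= B` always. Cross-side factors compare against
#' the healthy ROI: `MaxMax = Tmax - Tmax_healthy`,
#' `MaxMin = Tmax - Tmin_healthy`, the deviation of the affected maximum
#' from the healthy mean, and the difference of means.
#'
#' Ties at the maximum or minimum are resolved to the first cell in
#' row-major order (row 1 = image top), which fixes `D` deterministically;
#' for a constant ROI `A = C = 0` (no cell exceeds `theta = mean`).
#'
#' @param affected,healthy [breast_roi] objects (roles are checked when
#'   present); each needs at least 2 valid cells.
#' @return A named numeric vector of the 18 factor columns
#'   (`Max_Temperature`, `Min_temperature`, `Temperature_Range`, `Mean`,
#'   `Median`, `Standard_Deviation`, `Variance`, `Deviation_From_Mean`,
#'   `MaxMax`, `MaxMin`, `Deviation_Mean_Healthy`, `Mean_Difference`, `D`,
#'   `A`, `B`, `C`, `A/B`, `C/B`).
#' @export
extract_factors <- function(affected, healthy) {
  get_grid <- function(x) if (inherits(x, "breast_roi")) x$grid else x
  ga <- get_grid(affected); gh <- get_grid(healthy)
  stopifnot(inherits(ga, "thermogram"), inherits(gh, "thermogram"))
  if (inherits(affected, "breast_roi") && !is.na(affected$role) &&
      affected$role != "affected")
    stop("first argument must carry the affected role", call. = FALSE)
  va <- ga$values[ga$mask]
  vh <- gh$values[gh$mask]
  if (length(va) < 2L || length(vh) < 2L)
    stop("each ROI needs at least 2 valid cells", call. = FALSE)

  tmax <- max(va); tmin <- min(va)
  mu <- mean(va)
  med <- stats::median(va)
  n <- length(va)
  variance <- sum((va - mu)^2) / n         # population variance
  sdev <- sqrt(variance)

  # row-major first occurrence of max / min among valid cells
  vals <- ga$values
  vals[!ga$mask] <- NA
  # row-major scan: transpose so that column-major which() walks rows first
  tv <- t(vals)
  pos_of <- function(target) {
    k <- which(tv == target)[1L]
    ij <- arrayInd(k, dim(tv))
    c(row = ij[2L], col = ij[1L])
  }
  pmax_ <- pos_of(tmax)
  pmin_ <- pos_of(tmin)
  D <- sqrt(sum((pmax_ - pmin_)^2))

  theta <- mu + 0.5 * (tmax - mu)
  above <- ga$mask & !is.na(vals) & vals > theta
  B <- n
  C <- sum(above)
  A <- if (above[pmax_["row"], pmax_["col"]])
    sum(component8(above, pmax_)) else 0L

  muh <- mean(vh)
  out <- c(tmax, tmin, tmax - tmin, mu, med, sdev, variance, tmax - mu,
           tmax - max(vh), tmax - min(vh), tmax - muh, mu - muh,
           D, A, B, C, A / B, C / B)
  names(out) <- factor_names
  out
}

#' Build the per-patient factor table
#'
#' One row per patient: id, the 18 thermal factors, age, age at last
#' menstrual period, and the diagnosis. Patients whose factor extraction
#' fails are flagged, excluded, and reported in the `"failed"` attribute.
#'
#' @param records patient record data.frame (`patient_id`, `age`,
#'   `last_menstrual_period`, `diagnosis`, `affected_side`).
#' @param roi_pairs list (parallel to `records`) of
#'   `list(affected =, healthy =)` [breast_roi] pairs.
#' @return A data.frame (`check.names = FALSE`, so `A/B` and `C/B` appear
#'   verbatim) with attribute `"failed"` listing excluded patient ids.
#' @export
factor_table <- function(records, roi_pairs) {
  stopifnot(nrow(records) == length(roi_pairs))
  rows <- vector("list", nrow(records))
  failed <- character()
  for (i in seq_len(nrow(records))) {
    f <- tryCatch(extract_factors(roi_pairs[[i]]$affected,
                                  roi_pairs[[i]]$healthy),
                  error = function(e) {
                    warning(sprintf("patient %s excluded: %s",
                                    records$patient_id[i],
                                    conditionMessage(e)), call. = FALSE)
                    NULL
                  })
    if (is.null(f)) failed <- c(failed, records$patient_id[i]) else rows[[i]] <- f
  }
  keep <- !vapply(rows, is.null, logical(1))
  fm <- do.call(rbind, rows[keep])
  out <- data.frame(patient_id = records$patient_id[keep],
                    stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(fm)) out <- cbind(out, as.data.frame(fm, check.names = FALSE))
  out$age <- records$age[keep]
  out$last_menstrual_period <- records$last_menstrual_period[keep]
  out$diagnosis <- records$diagnosis[keep]
  rownames(out) <- NULL
  attr(out, "failed") <- failed
  out
}
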