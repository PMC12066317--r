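#' Streamline-VTA connectivity matrix
#'
#' A fiber is connected to a patient when any of its points falls inside
#' a voxel of the patient's (bilateral-union) VTA. Streamline segments
#' are densified by sampling at steps of at most half the smallest voxel
#' edge, so thin masks are not skipped between vertices.
#'
#' @param tract A `tractogram`.
#' @param vtas Named list of per-patient linear voxel index vectors on
#'   `grid` (from [patient_vta_voxels()]).
#' @param grid The `image_volume` (or `label_atlas`) the VTAs live on.
#' @return Logical matrix fibers x patients, dimnames = fiber ids,
#'   patient ids.
#' @export
streamline_vta_connectivity <- function(tract, vtas, grid) {
  if (inherits(grid, "label_atlas")) grid <- grid$volume
  if (tract$count == 0) stop("empty tractogram")
  fib_vox <- fiber_voxel_sets(tract, grid)
  npat <- length(vtas)
  conn <- matrix(FALSE, tract$count, npat,
                 dimnames = list(seq_len(tract$count), names(vtas)))
  g <- logical(prod(dim(grid$data)))
  for (j in seq_len(npat)) {
    g[vtas[[j]]] <- TRUE
    conn[, j] <- vapply(fib_vox, function(v) any(g[v]), logical(1))
    g[vtas[[j]]] <- FALSE
  }
  conn
}

# per-fiber unique linear voxel indices, after half-voxel densification
fiber_voxel_sets <- function(tract, grid) {
  step <- min(voxel_size(grid)) / 2
  lapply(tract$streamlines, function(s) {
    seg <- diff(s)
    len <- sqrt(rowSums(seg^2))
    pts <- list(s)
    for (i in which(len > step)) {
      nsub <- ceiling(len[i] / step)
      tt <- seq_len(nsub - 1) / nsub
      pts[[length(pts) + 1L]] <-
        cbind(s[i, 1] + tt * seg[i, 1], s[i, 2] + tt * seg[i, 2],
              s[i, 3] + tt * seg[i, 3])
    }
    idx <- world_to_linear_index(grid, do.call(rbind, pts))
    sort(unique(idx[!is.na(idx)]))
  })
}

#' Prevalence filter for fibers
#'
#' Keep a fiber iff it is connected to at least
#' `ceiling(fraction * n_patients)` patients' VTAs.
#'
#' @param conn Connectivity matrix from [streamline_vta_connectivity()].
#' @param fraction Prevalence fraction in (0, 1); default 0.2.
#' @return Integer vector of kept fiber ids (row indices).
#' @export
prevalence_filter <- function(conn, fraction = 0.2) {
  stopifnot(fraction > 0, fraction < 1)
  need <- ceiling(fraction * ncol(conn))
  which(rowSums(conn) >= need)
}

#' Fiber T-scores
#'
#' For each fiber, a pooled-variance two-sample t statistic comparing
#' outcome change between patients whose VTA the fiber intersects
#' (connected) and those it does not. Positive t means the connected
#' group improved more. Undefined scores (a group with < 2 members, or
#' zero pooled variance) are NaN with `flag`.
#'
#' @param conn Connectivity matrix (fibers x patients).
#' @param changes Outcome change per patient, aligned with `conn` columns.
#' @param fiber_ids Fibers to score (default: all rows).
#' @return Data frame with `fiber_id`, `t_score`, `n_connected`,
#'   `n_unconnected`, `flag`.
#' @export
fiber_t_scores <- function(conn, changes, fiber_ids = seq_len(nrow(conn))) {
  stopifnot(length(changes) == ncol(conn))
  cc <- conn[fiber_ids, , drop = FALSE]
  n <- ncol(cc)
  n1 <- rowSums(cc)
  n0 <- n - n1
  s1 <- as.vector(cc %*% changes)
  sq1 <- as.vector(cc %*% changes^2)
  s0 <- sum(changes) - s1
  sq0 <- sum(changes^2) - sq1
  m1 <- s1 / n1
  m0 <- s0 / n0
  ss1 <- sq1 - n1 * m1^2
  ss0 <- sq0 - n0 * m0^2
  sp2 <- (ss1 + ss0) / (n1 + n0 - 2)
  t <- (m1 - m0) / sqrt(sp2 * (1 / n1 + 1 / n0))
  bad_n <- n1 < 2 | n0 < 2
  bad_v <- !bad_n & sp2 <= 0
  t[bad_n | bad_v] <- NaN
  data.frame(fiber_id = fiber_ids, t_score = t,
             n_connected = n1, n_unconnected = n0,
             flag = ifelse(bad_n, "group_too_small",
                           ifelse(bad_v, "zero_variance", "ok")),
             stringsAsFactors = FALSE)
}

#' Select the top fraction of fibers by |T|
#'
#' Takes the top `ceiling(fraction * n)` of the supplied (finite-scored)
#' fibers by absolute T-score; ties are broken by ascending fiber id for
#' determinism.
#'
#' @param scores Data frame from [fiber_t_scores()].
#' @param fraction Fraction to select; default 0.3.
#' @return Integer vector of selected fiber ids.
#' @export
select_top_fraction <- function(scores, fraction = 0.3) {
  ok <- is.finite(scores$t_score)
  sc <- scores[ok, ]
  n_sel <- ceiling(fraction * nrow(sc))
  if (n_sel == 0) return(integer(0))
  ord <- order(-abs(sc$t_score), sc$fiber_id)
  sort(sc$fiber_id[ord[seq_len(n_sel)]])
}

#' Predict a held-out patient's outcome from trained fiber scores
#'
#' The prediction is the mean T-score over the trained selected fibers
#' connected to the held-out patient's VTA; 0 (flagged) when none are
#' connected.
#'
#' @param scores Trained data frame from [fiber_t_scores()].
#' @param selected Selected fiber ids (from [select_top_fraction()]).
#' @param conn_row Logical connectivity vector of the held-out patient
#'   against all fibers (same indexing as the training tractogram).
#' @return List with `prediction` and `flag`.
#' @export
predict_from_fibers <- function(scores, selected, conn_row) {
  sel <- scores[scores$fiber_id %in% selected &
                  is.finite(scores$t_score), ]
  hit <- sel[conn_row[sel$fiber_id], ]
  if (nrow(hit) == 0)
    return(list(prediction = 0, flag = "no_connected_fibers"))
  list(prediction = mean(hit$t_score), flag = "ok")
}

fit_fiber_model <- function(conn, changes, prevalence = 0.2, top = 0.3) {
  kept <- prevalence_filter(conn, prevalence)
  scores <- fiber_t_scores(conn, changes, kept)
  selected <- select_top_fraction(scores, top)
  list(scores = scores, kept = kept, selected = selected)
}

#' Cross-validated fiber-model outcome prediction
#'
#' Per fold, the prevalence filter, T-scores and top-fraction selection
#' are recomputed on the training patients only; held-out patients are
#' predicted via [predict_from_fibers()]. R is the Pearson correlation
#' of predicted vs observed (Spearman via `cor_method`).
#'
#' @param cohort A `dbs_cohort`.
#' @param outcome Scale name (e.g. `"HAMA"`).
#' @param scheme `"loocv"` or `"kfold"`.
#' @param k Number of folds for k-fold.
#' @param seed Seed fixing the k-fold partition.
#' @param prevalence,top Filter fractions.
#' @param measure `"change"` or `"improvement"`.
#' @param cor_method `"pearson"` (default) or `"spearman"`.
#' @param conn Optional precomputed connectivity matrix (it does not
#'   depend on outcomes, so sharing it across folds leaks nothing).
#' @return A `cv_result` list: `predicted`, `observed`, `fold`, `R`,
#'   `p_value`, `scheme`, `k`, `seed`, `flags`.
#' @export
crossvalidate_fibers <- function(cohort, outcome = "HAMA",
                                 scheme = c("loocv", "kfold"), k = 10,
                                 seed = 1, prevalence = 0.2, top = 0.3,
                                 measure = "change",
                                 cor_method = "pearson", conn = NULL) {
  scheme <- match.arg(scheme)
  changes <- clinical_outcome(cohort$clinical, outcome, measure)
  n <- length(changes)
  if (n < 8) stop("need at least 8 patients for cross-validation")
  if (is.null(conn)) {
    vtas <- patient_vta_voxels(cohort)
    conn <- streamline_vta_connectivity(cohort$tractogram, vtas,
                                        cohort$atlas$volume)
  }
  folds <- make_folds(n, scheme, k, seed)
  pred <- numeric(n); flags <- character(n)
  for (f in unique(folds)) {
    test <- which(folds == f)
    train <- which(folds != f)
    fit <- fit_fiber_model(conn[, train, drop = FALSE], changes[train],
                           prevalence, top)
    for (i in test) {
      pr <- predict_from_fibers(fit$scores, fit$selected, conn[, i])
      pred[i] <- pr$prediction; flags[i] <- pr$flag
    }
  }
  cv_result(pred, changes, folds, scheme, k, seed, cor_method)
}

make_folds <- function(n, scheme, k, seed) {
  if (scheme == "loocv") return(seq_len(n))
  set.seed(seed)
  sample(rep_len(seq_len(k), n))
}

cv_result <- function(predicted, observed, folds, scheme, k, seed,
                      cor_method = "pearson") {
  flag <- "ok"
  if (stats::sd(predicted) == 0 || stats::sd(observed) == 0) {
    R <- NaN; p <- NaN; flag <- "constant_predictions"
  } else if (cor_method == "spearman") {
    sp <- spearman_cor(predicted, observed)
    R <- sp$rho; p <- sp$p_value
  } else {
    ct <- stats::cor.test(predicted, observed)
    R <- unname(ct$estimate); p <- ct$p.value
  }
  structure(list(predicted = predicted, observed = observed, fold = folds,
                 R = R, p_value = p, scheme = scheme,
                 k = if (scheme == "kfold") k else NA_integer_,
                 seed = seed, flag = flag),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s (n = %d): R = %.3f, p = %.3g\n",
              if (x$scheme == "kfold") sprintf("%d-fold CV", x$k) else "LOOCV",
              length(x$predicted), x$R, x$p_value))
  invisible(x)
}
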