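# PCA with scree-based dimensionality choice -----------------------------------

#' PCA of a response matrix with a scree-test component choice
#'
#' Principal components of the odorant x ORN response matrix (odorants as
#' observations). The number of retained components is chosen by the scree
#' elbow, operationalized as the largest second difference of the
#' explained-variance curve (the point where the drop between consecutive
#' explained variances falls off most sharply); callers can override `k`.
#' Centering is on and variable scaling off by default, since responses
#' share units.
#'
#' @param responses numeric matrix, odorants in rows, ORNs in columns.
#' @param center,scale. passed to [stats::prcomp()].
#' @param k optional fixed component count overriding the scree choice.
#' @return list of class `scree_pca`: the `prcomp` fit, `explained_variance`
#'   (per component), `k`.
#' @export
pca_with_scree <- function(responses, center = TRUE, scale. = FALSE, k = NULL) {
  if (nrow(responses) < 2) stop("need at least two odorants")
  if (all(apply(responses, 2, stats::var) == 0)) {
    stop("constant response matrix has no principal components")
  }
  fit <- stats::prcomp(responses, center = center, scale. = scale.)
  ev <- fit$sdev^2
  if (is.null(k)) k <- scree_elbow(ev)
  structure(list(fit = fit, explained_variance = ev, k = k),
            class = "scree_pca")
}

#' Scree elbow of an explained-variance series
#'
#' The retained dimensionality is the index at which the drop between
#' consecutive explained variances decreases the most (largest second
#' difference of the decreasing curve).
#'
#' @param ev explained variances, decreasing.
#' @return the selected component count.
#' @export
scree_elbow <- function(ev) {
  if (length(ev) < 3) return(1L)
  drops <- -diff(ev)                 # drop after each component
  second <- -diff(drops)             # how much the drop falls off
  as.integer(which.max(drops[-length(drops)] - drops[-1]))
}

# Affinity propagation ----------------------------------------------------------

#' Affinity-propagation clustering
#'
#' Exemplar-based clustering by responsibility/availability message passing;
#' the number of clusters is not an input but emerges from the preference
#' (self-similarity). Updates are damped; convergence is declared when the
#' exemplar set is stable for `conv_iter` consecutive iterations.
#'
#' @param S square similarity matrix (larger = more similar); typically the
#'   negative squared Euclidean distance.
#' @param preference self-similarity placed on the diagonal; default the
#'   median of the off-diagonal similarities.
#' @param damping damping factor in `[0.5, 1)` (default 0.9).
#' @param max_iter,conv_iter iteration limits.
#' @return list of class `affinity_propagation`: `exemplars` (indices or
#'   names), `labels` (exemplar of each point), `converged`, `iterations`.
#' @export
affinity_propagation <- function(S, preference = NULL, damping = 0.9,
                                 max_iter = 500, conv_iter = 50) {
  stopifnot(is.matrix(S), nrow(S) == ncol(S), damping >= 0.5, damping < 1)
  n <- nrow(S)
  nm <- rownames(S)
  if (n == 1L) {
    return(structure(list(exemplars = 1L, labels = 1L, converged = TRUE,
                          iterations = 0L, names = nm),
                     class = "affinity_propagation"))
  }
  off <- S[row(S) != col(S)]
  if (diff(range(off)) == 0) {
    # indistinguishable points: one cluster, first point as exemplar
    return(structure(list(exemplars = 1L, labels = rep(1L, n),
                          converged = TRUE, iterations = 0L, names = nm),
                     class = "affinity_propagation"))
  }
  if (is.null(preference)) preference <- stats::median(off)
  diag(S) <- preference
  # tiny deterministic jitter breaks ties between identical points
  jit <- with_seed(0L, matrix(stats::runif(n * n), n, n))
  S <- S + (abs(S) + 1e-12) * .Machine$double.eps * 100 * jit
  R <- matrix(0, n, n); A <- matrix(0, n, n)
  prev <- NULL; stable <- 0L; it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    # responsibilities
    AS <- A + S
    max1 <- apply(AS, 1, max)
    which1 <- max.col(AS, ties.method = "first")
    AS2 <- AS
    AS2[cbind(seq_len(n), which1)] <- -Inf
    max2 <- apply(AS2, 1, max)
    Rnew <- S - max1
    Rnew[cbind(seq_len(n), which1)] <- S[cbind(seq_len(n), which1)] - max2
    R <- damping * R + (1 - damping) * Rnew
    # availabilities
    Rp <- pmax(R, 0); diag(Rp) <- diag(R)
    cs <- colSums(Rp)
    Anew <- matrix(cs, n, n, byrow = TRUE) - Rp
    dA <- diag(Anew)
    Anew <- pmin(Anew, 0)
    diag(Anew) <- dA
    A <- damping * A + (1 - damping) * Anew
    ex <- which(diag(A + R) > 0)
    if (identical(ex, prev)) stable <- stable + 1L else stable <- 0L
    prev <- ex
    if (stable >= conv_iter && length(ex)) break
  }
  converged <- stable >= conv_iter && length(prev) > 0
  ex <- as.integer(unname(prev))
  if (!length(ex)) ex <- unname(which.max(diag(A + R)))
  labels <- ex[max.col(S[, ex, drop = FALSE], ties.method = "first")]
  labels[ex] <- ex  # exemplars belong to their own cluster
  labels <- as.integer(unname(labels))
  structure(list(exemplars = ex, labels = labels, converged = converged,
                 iterations = it, names = nm),
            class = "affinity_propagation")
}

#' @export
print.affinity_propagation <- function(x, ...) {
  cat(sprintf("<affinity_propagation> %d cluster(s), %s after %d iterations\n",
              length(x$exemplars),
              if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

#' Negative squared Euclidean similarity matrix
#'
#' @param x numeric matrix, observations in rows.
#' @return similarity matrix `-|xi - xj|^2`.
#' @export
neg_sq_euclidean <- function(x) {
  d <- as.matrix(stats::dist(x))^2
  -d
}

# Descriptor-space k-means --------------------------------------------------------

#' K-means clustering of odorants in descriptor space
#'
#' Best-of-restarts k-means, deterministic given the seed.
#'
#' @param descriptors odorant x descriptor matrix.
#' @param k number of clusters.
#' @param seed integer seed.
#' @param restarts number of random starts.
#' @return a [stats::kmeans()] fit.
#' @export
kmeans_descriptor_clusters <- function(descriptors, k, seed = 1, restarts = 20) {
  if (k <= 0) stop("k must be positive")
  if (k > nrow(descriptors)) stop("k exceeds the number of odorants")
  if (k == nrow(descriptors)) {
    # one point per cluster: seed each centre with a point (Hartigan-Wong
    # needs k < n)
    return(with_seed(seed, stats::kmeans(descriptors, centers = descriptors,
                                         iter.max = 10, algorithm = "Lloyd")))
  }
  with_seed(seed, stats::kmeans(descriptors, centers = k, nstart = restarts))
}

# Centroid back-projection ---------------------------------------------------------

#' Back-project cluster centroids into ORN space
#'
#' Cluster centroids in the retained component space are mapped back to ORN
#' space through the transpose of the loading map, re-adding the centering
#' offset: `x = centroid %*% t(W_k) + mean`. A singleton cluster back-projects
#' to that odorant's rank-k reconstruction; a centroid at the component-space
#' origin back-projects to the mean response vector.
#'
#' @param pca a [pca_with_scree()] fit.
#' @param labels cluster label per odorant (row of the PCA input).
#' @return matrix, one row per cluster, columns = ORNs.
#' @export
backproject_centroids <- function(pca, labels) {
  fit <- pca$fit; k <- pca$k
  scores <- fit$x[, seq_len(k), drop = FALSE]
  cl <- sort(unique(labels))
  cent <- t(vapply(cl, function(c)
    colMeans(scores[labels == c, , drop = FALSE]), numeric(k)))
  if (k == 1) cent <- matrix(cent, ncol = 1)  # vapply collapses to vector
  W <- fit$rotation[, seq_len(k), drop = FALSE]
  back <- cent %*% t(W)
  if (!is.logical(fit$scale)) back <- sweep(back, 2, fit$scale, "*")
  if (!is.logical(fit$center)) back <- sweep(back, 2, fit$center, "+")
  rownames(back) <- as.character(cl)
  back
}

# Otsu threshold -------------------------------------------------------------------

#' Otsu's threshold on continuous values
#'
#' One-dimensional threshold maximizing the between-class variance
#' `w0 * w1 * (mu0 - mu1)^2` — a discrete analogue of Fisher's discriminant.
#' On continuous inputs, candidate cuts are the midpoints between consecutive
#' sorted unique values (exact search); for large inputs a binned variant is
#' available through `bins`.
#'
#' @param values numeric vector with at least two distinct values.
#' @param bins optional histogram bin count for the binned variant (candidate
#'   cuts are then interior bin edges).
#' @return the threshold; points strictly above it form the upper class.
#' @export
otsu_threshold <- function(values, bins = NULL) {
  u <- sort(unique(values))
  if (length(u) < 2) stop("Otsu threshold undefined: all values equal")
  cuts <- if (is.null(bins)) {
    (u[-1] + u[-length(u)]) / 2
  } else {
    br <- seq(min(values), max(values), length.out = bins + 1)
    br[-c(1, length(br))]
  }
  n <- length(values)
  bcv <- vapply(cuts, function(tau) {
    lo <- values <= tau
    w0 <- sum(lo) / n; w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) return(-Inf)
    w0 * w1 * (mean(values[lo]) - mean(values[!lo]))^2
  }, numeric(1))
  cuts[which.max(bcv)]
}

# The fitted odor-tuning model -------------------------------------------------------

#' Fit the ORN odor-tuning cluster model
#'
#' The full receptive-field pipeline: PCA of the odorant x ORN response
#' matrix with a scree-test dimensionality choice, affinity-propagation
#' clustering of odorants in the retained component space (similarity =
#' negative squared Euclidean distance), back-projection of each cluster
#' centroid into ORN space through the inverse transformation, and a single
#' global Otsu threshold over the pooled back-projected coordinates calling
#' the encoding-ORN set of each cluster.
#'
#' @param responses odorant x ORN response matrix.
#' @param center,scale. PCA flags (see [pca_with_scree()]).
#' @param k optional fixed component count (default: scree choice).
#' @param preference,damping,max_iter affinity-propagation controls.
#' @param odorant_class optional named vector of chemical classes per
#'   odorant; clusters are then annotated with their majority class.
#' @return object of class `orn_tuning` with components `pca`, `clustering`,
#'   `labels` (odorant -> cluster id), `exemplars`, `centroids_orn`
#'   (back-projections), `threshold`, `encoding` (ORN set per cluster),
#'   `cluster_class`.
#' @export
orn_tuning <- function(responses, center = TRUE, scale. = FALSE, k = NULL,
                       preference = NULL, damping = 0.9, max_iter = 1000,
                       odorant_class = NULL) {
  responses <- as.matrix(responses)
  pca <- pca_with_scree(responses, center = center, scale. = scale., k = k)
  scores <- pca$fit$x[, seq_len(pca$k), drop = FALSE]
  ap <- affinity_propagation(neg_sq_euclidean(scores), preference = preference,
                             damping = damping, max_iter = max_iter)
  labels <- ap$labels
  back <- backproject_centroids(pca, labels)
  # normalise each centroid back-projection to [0, 1] so one global
  # threshold is comparable across clusters
  norm <- t(apply(back, 1, function(x) {
    r <- range(x)
    if (diff(r) == 0) rep(0, length(x)) else (x - r[1]) / diff(r)
  }))
  colnames(norm) <- colnames(back)
  tau <- otsu_threshold(as.vector(norm))
  encoding <- apply(norm, 1, function(x) colnames(norm)[x > tau],
                    simplify = FALSE)
  cluster_class <- NULL
  if (!is.null(odorant_class)) {
    cluster_class <- vapply(rownames(back), function(c) {
      cls <- odorant_class[rownames(responses)[labels == as.integer(c)]]
      names(sort(table(cls), decreasing = TRUE))[1]
    }, character(1))
  }
  structure(
    list(pca = pca, clustering = ap,
         labels = stats::setNames(labels, rownames(responses)),
         exemplars = rownames(responses)[ap$exemplars],
         centroids_orn = back, centroids_scaled = norm, threshold = tau,
         encoding = encoding, cluster_class = cluster_class,
         responses = responses),
    class = "orn_tuning")
}

#' @export
print.orn_tuning <- function(x, ...) {
  cat(sprintf("<orn_tuning> %d odorants x %d ORNs: %d components, %d clusters, Otsu threshold %.4f\n",
              nrow(x$responses), ncol(x$responses), x$pca$k,
              length(x$exemplars), x$threshold))
  invisible(x)
}

#' @export
summary.orn_tuning <- function(object, ...) {
  print(object)
  ev <- object$pca$explained_variance
  cat(sprintf("  explained variance (first %d): %s\n", min(5, length(ev)),
              paste(sprintf("%.1f%%", 100 * ev[seq_len(min(5, length(ev)))] /
                              sum(ev)), collapse = ", ")))
  for (c in rownames(object$centroids_orn)) {
    cls <- if (!is.null(object$cluster_class))
      sprintf(" [%s]", object$cluster_class[[c]]) else ""
    cat(sprintf("  cluster %s%s (exemplar %s): %d odorants; encoding ORNs: %s\n",
                c, cls, rownames(object$responses)[as.integer(c)],
                sum(object$labels == as.integer(c)),
                paste(object$encoding[[c]], collapse = ", ")))
  }
  invisible(object)
}

#' Assign new odorants to fitted tuning clusters
#'
#' Projects new odorant response vectors into the retained component space
#' and assigns each to the cluster of the nearest exemplar.
#'
#' @param object an [orn_tuning()] fit.
#' @param newdata matrix of odorant response vectors (columns matching the
#'   training ORNs).
#' @param ... unused.
#' @return named vector of cluster ids.
#' @export
predict.orn_tuning <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  sc <- stats::predict(object$pca$fit, newdata)[, seq_len(object$pca$k),
                                                drop = FALSE]
  ex_sc <- object$pca$fit$x[object$clustering$exemplars, seq_len(object$pca$k),
                            drop = FALSE]
  d <- outer(rowSums(sc^2), rowSums(ex_sc^2), "+") - 2 * sc %*% t(ex_sc)
  idx <- apply(d, 1, which.min)
  stats::setNames(object$clustering$exemplars[idx], rownames(newdata))
}

# Cross-validation against private odorants ---------------------------------------

#' Cross-validate encoding sets with single-ORN activators
#'
#' Privately activating odorants (each known to activate a single ORN at low
#' concentration) test the predicted receptive fields: an activator agrees
#' with the model when its ORN lies in the encoding set of the cluster whose
#' chemical class matches the odorant's. Classes absent from the trained
#' clusters are reported as unpredictable (regions of odor space not
#' sampled); unknown ORNs are skipped with a warning.
#'
#' @param model an [orn_tuning()] fit with `cluster_class` annotation (fit
#'   with `odorant_class`).
#' @param activators `data.frame` with columns `odorant`, `orn`, `class`.
#' @return `data.frame` of class `tuning_crossval` with a `status` per
#'   activator (`"agree"`, `"disagree"`, `"unpredictable"`, `"skipped"`) and
#'   an `agreement` attribute (fraction agree among predictable ones).
#' @export
crossvalidate_private_odorants <- function(model, activators) {
  if (is.null(model$cluster_class)) {
    stop("model lacks cluster class annotation; fit with odorant_class")
  }
  orns <- colnames(model$responses)
  status <- character(nrow(activators))
  for (i in seq_len(nrow(activators))) {
    orn <- activators$orn[i]; cls <- activators$class[i]
    if (!orn %in% orns) {
      warning("unknown ORN skipped: ", orn)
      status[i] <- "skipped"; next
    }
    hit <- names(model$cluster_class)[model$cluster_class == cls]
    if (!length(hit)) { status[i] <- "unpredictable"; next }
    inset <- any(vapply(hit, function(h) orn %in% model$encoding[[h]],
                        logical(1)))
    status[i] <- if (inset) "agree" else "disagree"
  }
  out <- cbind(activators, status = status, stringsAsFactors = FALSE)
  pred <- status %in% c("agree", "disagree")
  attr(out, "agreement") <- if (any(pred)) mean(status[pred] == "agree") else NA
  class(out) <- c("tuning_crossval", "data.frame")
  out
}

#' @export
print.tuning_crossval <- function(x, ...) {
  cat(sprintf("<tuning_crossval> %d activators: %d agree, %d disagree, %d unpredictable, %d skipped\n",
              nrow(x), sum(x$status == "agree"), sum(x$status == "disagree"),
              sum(x$status == "unpredictable"), sum(x$status == "skipped")))
  if (!is.na(attr(x, "agreement"))) {
    cat(sprintf("  agreement among predictable: %.0f%%\n",
                100 * attr(x, "agreement")))
  }
  invisible(x)
}
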