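#' Breed reference allele-frequency panel
#'
#' Per-breed pooled frequencies of the counted allele at each panel marker,
#' clamped away from 0 and 1 so that no genotype has log-probability
#' \eqn{-\infty} under any breed. Sites with zero called genotypes in a
#' breed are recorded and that breed's frequency there is set to NA; such
#' sites are skipped in that breed's likelihood contribution via clamping
#' to 0.5 (maximally uninformative).
#'
#' @param g a \code{geno_matrix} of the labelled reference individuals
#' @param labels per-sample breed labels
#' @param marker_ids panel markers (default: all markers of \code{g});
#'   may be a \code{panel_result}
#' @param eps clamp: frequencies forced into [eps, 1 - eps]; default 1e-4
#' @return a \code{breed_freq_panel}: list with \code{freqs} (K x M
#'   matrix, rows = breeds), \code{breeds}, \code{markers},
#'   \code{n_unobserved} (count of breed-site cells with no genotypes).
#' @export
panel_frequencies <- function(g, labels = breed_labels(g),
                              marker_ids = NULL, eps = 1e-4) {
  if (inherits(marker_ids, "panel_result")) marker_ids <- marker_ids$marker_id
  if (!is.null(marker_ids)) g <- subset_geno(g, marker_ids = marker_ids)
  labels <- as.character(labels)
  breeds <- unique(stats::na.omit(labels))
  if (length(breeds) == 0L) stop("no labelled reference individuals")
  freqs <- matrix(NA_real_, nrow = length(breeds), ncol = ncol(g$dosage),
                  dimnames = list(breeds, g$map$marker_id))
  for (i in seq_along(breeds)) {
    freqs[i, ] <- counted_freq(g$dosage[which(labels == breeds[i]), ,
                                        drop = FALSE])
  }
  n_unobserved <- sum(is.na(freqs))
  clamped <- pmin(pmax(freqs, eps), 1 - eps)
  clamped[is.na(freqs)] <- 0.5
  structure(list(freqs = clamped, breeds = breeds,
                 markers = g$map$marker_id, eps = eps,
                 n_unobserved = n_unobserved),
            class = "breed_freq_panel")
}

#' @exportS3Method base::print
print.breed_freq_panel <- function(x, ...) {
  cat(sprintf("breed_freq_panel: %d breeds x %d markers (eps = %g)\n",
              length(x$breeds), length(x$markers), x$eps))
  invisible(x)
}

#' Estimate genomic breed composition by supervised admixture
#'
#' Maximum-likelihood ancestry fractions for one or more individuals
#' against fixed reference breed frequencies. For an individual with
#' dosages \eqn{g_j} the log-likelihood is
#' \deqn{\ell(q) = \sum_j g_j \log\Big(\sum_k q_k f_{kj}\Big)
#'   + (2 - g_j)\log\Big(1 - \sum_k q_k f_{kj}\Big)}
#' maximised over the simplex by EM: the E-step allocates each allele copy
#' to breeds in proportion to \eqn{q_k f_{kj}} (or \eqn{q_k(1-f_{kj})} for
#' the reference allele), the M-step renormalises. The likelihood is
#' concave in \eqn{q}, so a flat start \eqn{q_k = 1/K} suffices and the
#' log-likelihood is non-decreasing across iterations. Missing genotypes
#' are skipped.
#'
#' @param genotypes a \code{geno_matrix}, or an integer vector of dosages
#'   for a single individual aligned to \code{panel$markers}
#' @param panel a \code{\link{panel_frequencies}} result
#' @param max_iter maximum EM iterations; default 500
#' @param tol stop when the log-likelihood improves by less than this;
#'   default 1e-6
#' @return an object of class \code{gbc_fit}: list with \code{q}
#'   (n x K matrix of ancestry fractions), \code{loglik}, \code{n_iter},
#'   \code{converged} (per individual), \code{breeds}, \code{panel}.
#' @seealso \code{\link{purity_call}}, \code{\link{predict.gbc_fit}}
#' @export
fit_ancestry <- function(genotypes, panel, max_iter = 500, tol = 1e-6) {
  if (inherits(genotypes, "geno_matrix")) {
    common <- intersect(panel$markers, genotypes$map$marker_id)
    if (length(common) == 0L)
      stop("no overlapping markers between genotypes and reference panel")
    G <- genotypes$dosage[, match(common, genotypes$map$marker_id),
                          drop = FALSE]
    Fm <- panel$freqs[, match(common, panel$markers), drop = FALSE]
    ids <- genotypes$samples$sample_id
  } else {
    G <- matrix(as.integer(genotypes), nrow = 1)
    if (ncol(G) != length(panel$markers))
      stop("dosage vector length must match the panel marker count")
    Fm <- panel$freqs
    ids <- "ind1"
  }
  K <- nrow(Fm); n <- nrow(G); M <- ncol(G)
  W <- !is.na(G)
  if (any(rowSums(W) == 0L))
    stop("individual(s) with zero non-missing overlapping markers: ",
         paste(ids[rowSums(W) == 0L], collapse = ", "))
  Gz <- G; Gz[!W] <- 0L
  G2 <- (2L - G); G2[!W] <- 0L
  storage.mode(Gz) <- "double"; storage.mode(G2) <- "double"
  tF <- t(Fm)            # M x K
  tF1 <- 1 - tF
  Q <- matrix(1 / K, nrow = n, ncol = K, dimnames = list(ids, rownames(Fm)))
  denom <- 2 * rowSums(W)
  ll_of <- function(Q) {
    P <- Q %*% t(tF)     # n x M
    rowSums(Gz * log(P)) + rowSums(G2 * log1p(-P))
  }
  ll <- ll_of(Q)
  if (any(!is.finite(ll))) {
    P0 <- Q %*% t(tF)
    bad <- which(!is.finite(Gz * log(P0) + G2 * log1p(-P0)), arr.ind = TRUE)
    stop("non-finite log-likelihood; offending site: ",
         colnames(G)[bad[1, 2]])
  }
  n_iter <- rep(0L, n); converged <- rep(FALSE, n)
  for (it in seq_len(max_iter)) {
    P <- Q %*% t(tF)
    A <- (Gz / P) %*% tF        # n x K: expected ALT copies per breed / q_k
    B <- (G2 / (1 - P)) %*% tF1
    Qn <- Q * (A + B) / denom
    Qn <- Qn / rowSums(Qn)      # guard renormalisation
    lln <- ll_of(Qn)
    active <- !converged
    just <- active & (lln - ll < tol)
    converged[just] <- TRUE
    n_iter[active] <- it
    improve <- lln >= ll - 1e-9
    Q[active & improve, ] <- Qn[active & improve, ]
    ll[active & improve] <- lln[active & improve]
    if (all(converged)) break
  }
  structure(list(q = Q, loglik = ll, n_iter = n_iter,
                 converged = converged, breeds = rownames(Fm),
                 n_markers = M),
            class = "gbc_fit")
}

#' @exportS3Method base::print
print.gbc_fit <- function(x, ...) {
  top <- x$breeds[max.col(x$q)]
  pur <- apply(x$q, 1, max)
  cat(sprintf(
    "Supervised-admixture GBC fit: %d individuals, K = %d breeds, %d markers\n",
    nrow(x$q), length(x$breeds), x$n_markers))
  cat(sprintf("  converged: %d/%d; median purity %.3f\n",
              sum(x$converged), nrow(x$q), stats::median(pur)))
  print(utils::head(data.frame(sample = rownames(x$q), top_breed = top,
                               purity = round(pur, 4)), 10),
        row.names = FALSE)
  invisible(x)
}

#' @export
coef.gbc_fit <- function(object, ...) object$q

#' @export
summary.gbc_fit <- function(object, threshold = 0.95, ...) {
  pur <- apply(object$q, 1, max)
  out <- data.frame(
    sample_id = rownames(object$q),
    top_breed = object$breeds[max.col(object$q)],
    purity = pur,
    purity_call = ifelse(pur >= threshold, "pure", "admixed"),
    loglik = object$loglik,
    n_iter = object$n_iter,
    converged = object$converged,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Predict breed membership from a GBC fit
#'
#' @param object a \code{gbc_fit}
#' @param ... unused
#' @return character vector: the breed with the largest ancestry fraction
#'   per individual.
#' @export
predict.gbc_fit <- function(object, ...) {
  stats::setNames(object$breeds[max.col(object$q)], rownames(object$q))
}

#' Purity call from ancestry estimates
#'
#' An individual is called \code{"pure"} when its largest ancestry
#' fraction reaches the threshold (default 95\%), else \code{"admixed"}.
#'
#' @param fit a \code{gbc_fit} (or a numeric simplex vector for one
#'   individual)
#' @param threshold purity threshold; default 0.95
#' @return character vector of \code{"pure"}/\code{"admixed"}.
#' @export
purity_call <- function(fit, threshold = 0.95) {
  pur <- if (inherits(fit, "gbc_fit")) apply(fit$q, 1, max) else max(fit)
  ifelse(pur >= threshold, "pure", "admixed")
}

#' Stratified train/test split
#'
#' Splits sample indices into a training and test set, stratified by
#' label, deterministic under \code{seed}. Per label, the training count is
#' \code{round(fraction * n)}.
#'
#' @param labels per-sample labels
#' @param fraction training fraction; default 0.7
#' @param seed RNG seed
#' @return list with integer index vectors \code{train} and \code{test}.
#' @export
split_train_test <- function(labels, fraction = 0.7, seed = 1) {
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  labels <- as.character(labels)
  set.seed(seed)
  train <- integer(0)
  for (b in unique(labels)) {
    idx <- which(labels == b)
    k <- round(fraction * length(idx))
    train <- c(train, sort(sample(idx, k)))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train))
}

#' Breed-assignment accuracy of a classification method
#'
#' Trains on the labelled training individuals and reports the fraction of
#' test individuals assigned to their true breed. \code{"admixture"} fits
#' reference frequencies on the training set and assigns each test
#' individual to its argmax ancestry breed; \code{"rf"} and \code{"mlp"}
#' are off-the-shelf Random Forest / single-hidden-layer perceptron
#' classifiers on mean-imputed dosage vectors.
#'
#' @param method one of \code{"admixture"}, \code{"rf"}, \code{"mlp"}
#' @param g a \code{geno_matrix} with breed labels
#' @param split a list with \code{train}/\code{test} indices from
#'   \code{\link{split_train_test}}
#' @param seed RNG seed for the stochastic classifiers
#' @return list with \code{accuracy}, \code{predicted}, \code{truth}.
#' @export
evaluate_assignment <- function(method = c("admixture", "rf", "mlp"),
                                g, split, seed = 1) {
  method <- match.arg(method)
  labels <- breed_labels(g)
  tr <- split$train; te <- split$test
  truth <- labels[te]
  if (method == "admixture") {
    gtr <- subset_geno(g, sample_ids = g$samples$sample_id[tr])
    gte <- subset_geno(g, sample_ids = g$samples$sample_id[te])
    pan <- panel_frequencies(gtr, labels[tr])
    fit <- fit_ancestry(gte, pan)
    pred <- unname(predict(fit))
  } else {
    X <- g$dosage
    mu <- colMeans(X, na.rm = TRUE)
    mu[is.nan(mu)] <- 0
    for (j in which(colSums(is.na(X)) > 0L))
      X[is.na(X[, j]), j] <- mu[j]
    Xtr <- X[tr, , drop = FALSE]; Xte <- X[te, , drop = FALSE]
    ytr <- factor(labels[tr])
    set.seed(seed)
    if (method == "rf") {
      mod <- randomForest::randomForest(Xtr, ytr, ntree = 200)
      pred <- as.character(stats::predict(mod, Xte))
    } else {
      colnames(Xtr) <- colnames(Xte) <- paste0("m", seq_len(ncol(Xtr)))
      mod <- nnet::nnet(Xtr, nnet::class.ind(ytr), size = 8, decay = 0.01,
                        maxit = 300, MaxNWts = 200000, trace = FALSE)
      pr <- stats::predict(mod, Xte)
      pred <- levels(ytr)[max.col(pr)]
    }
  }
  list(accuracy = mean(pred == truth), predicted = pred, truth = truth)
}
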