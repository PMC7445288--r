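# Mutational-signature extraction by Kullback-Leibler NMF and catalog matching.

# Generalized KL divergence D(V || WH), with 0 log 0 = 0.
.kl_div <- function(V, WH) {
  WH <- pmax(WH, 1e-12)
  pos <- V > 0
  sum(V[pos] * log(V[pos] / WH[pos])) - sum(V) + sum(WH)
}

.nmf_run <- function(V, k, seed, max_iter, rel_tol) {
  p <- nrow(V); n <- ncol(V)
  init <- with_seed(seed, list(W = matrix(stats::runif(p * k, 0.1, 1), p, k),
                               H = matrix(stats::runif(k * n, 0.1, 1), k, n)))
  W <- init$W; H <- init$H
  eps <- 1e-12
  trace <- numeric(0)
  prev <- Inf
  for (it in seq_len(max_iter)) {
    WH <- pmax(W %*% H, eps)
    W <- W * ((V / WH) %*% t(H)) /
      matrix(pmax(rowSums(H), eps), p, k, byrow = TRUE)
    W <- pmax(W, eps)
    WH <- pmax(W %*% H, eps)
    H <- H * (t(W) %*% (V / WH)) /
      matrix(pmax(colSums(W), eps), k, n, byrow = FALSE)
    H <- pmax(H, eps)
    obj <- .kl_div(V, W %*% H)
    trace <- c(trace, obj)
    if (is.finite(prev) && abs(prev - obj) <= rel_tol * max(abs(prev), 1e-12)) {
      prev <- obj
      break
    }
    prev <- obj
  }
  # Column-normalize W, absorbing the scale into H.
  sc <- colSums(W)
  W <- sweep(W, 2, sc, "/")
  H <- sweep(H, 1, sc, "*")
  list(W = W, H = H, objective = prev, objective_trace = trace)
}

#' Extract mutational signatures by KL-divergence NMF
#'
#' Factorizes the 96 x n_samples count matrix `V = t(spectrum)` as `W %*% H`
#' with multiplicative updates minimizing the generalized Kullback-Leibler
#' divergence (the standard objective for count spectra). The best of
#' `n_restarts` random initialisations (ties broken by lowest restart index)
#' is kept; `W` columns are normalised to probability vectors with the scale
#' absorbed into the exposures `H`. Fully deterministic given `seed`.
#'
#' @param spectrum samples x 96 matrix from [build_spectrum()].
#' @param k number of signatures, `1 <= k <= min(96, n_samples)`.
#' @param n_restarts number of random restarts (default 10).
#' @param seed integer seed.
#' @param max_iter iteration cap per restart (default 2000).
#' @param rel_tol relative objective-change stopping tolerance (default 1e-8).
#' @return an object of class `signature_set`: list with `W` (96 x k, columns
#'   sum to 1), `H` (k x n_samples), `k`, and `objective_trace` (per-iteration
#'   KL divergence of the best restart, non-increasing).
#' @export
nmf_extract <- function(spectrum, k, n_restarts = 10, seed = 1L,
                        max_iter = 2000, rel_tol = 1e-8) {
  V <- t(unclass(spectrum)) # 96 x n
  if (!.is_count(k) || k < 1L) .stopf("k must be a positive integer")
  if (k > min(nrow(V), ncol(V)))
    .stopf("k = %d exceeds min(96, n_samples) = %d", k, min(nrow(V), ncol(V)))
  if (all(V == 0)) .stopf("spectrum is all zero; nothing to factorize")
  runs <- lapply(seq_len(n_restarts), function(r)
    .nmf_run(V, k, derive_seed(seed, sprintf("nmf_restart_%d", r)),
             max_iter, rel_tol))
  best <- which.min(vapply(runs, `[[`, 0, "objective")) # ties -> lowest index
  run <- runs[[best]]
  rownames(run$W) <- rownames(V)
  colnames(run$W) <- sprintf("signature_%d", seq_len(k))
  rownames(run$H) <- colnames(run$W)
  colnames(run$H) <- colnames(V)
  structure(list(W = run$W, H = run$H, k = k,
                 objective_trace = run$objective_trace),
            class = "signature_set")
}

.cosine <- function(x, y) {
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) return(0)
  sum(x * y) / (nx * ny)
}

#' Match extracted signatures to a reference catalog
#'
#' Cosine similarity of each signature column against every catalog vector;
#' a zero vector has similarity 0 by convention.
#'
#' @param signatures a `signature_set` (or a 96 x k matrix).
#' @param catalog named 96 x m matrix of reference probability vectors (e.g.
#'   from [read_signature_catalog()]).
#' @return data frame (`signature`, `best_match`, `cosine`) with the full
#'   similarity matrix as attribute `similarity`.
#' @export
cosine_match <- function(signatures, catalog) {
  W <- if (inherits(signatures, "signature_set")) signatures$W else signatures
  catalog <- as.matrix(catalog)
  if (ncol(catalog) < 1L) .stopf("reference catalog is empty")
  sim <- matrix(0, ncol(W), ncol(catalog),
                dimnames = list(colnames(W), colnames(catalog)))
  for (i in seq_len(ncol(W)))
    for (j in seq_len(ncol(catalog)))
      sim[i, j] <- .cosine(W[, i], catalog[, j])
  best <- max.col(sim, ties.method = "first")
  out <- data.frame(signature = colnames(W),
                    best_match = colnames(catalog)[best],
                    cosine = sim[cbind(seq_len(nrow(sim)), best)],
                    stringsAsFactors = FALSE)
  attr(out, "similarity") <- sim
  out
}

#' Read a 96-context reference signature catalog
#'
#' TSV dialect: first column `context` with the 96 canonical labels, one
#' column per named signature; each column is renormalised to sum to 1.
#' @param path TSV file.
#' @return 96 x m numeric matrix, rows in canonical context order.
#' @export
read_signature_catalog <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  .require_cols(df, "context", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$context
  miss <- setdiff(context_classes(), rownames(m))
  if (length(miss)) .stopf("%s: missing context rows (e.g. %s)", path, miss[1])
  m <- m[context_classes(), , drop = FALSE]
  sweep(m, 2, colSums(m), "/")
}

#' Write signature matrices as TSV
#' @param signatures a `signature_set`.
#' @param w_path,h_path output paths for W (contexts x signatures) and H
#'   (signatures x samples).
#' @return invisibly, the two paths.
#' @export
write_signatures_tsv <- function(signatures, w_path, h_path) {
  .write_tsv(data.frame(context = rownames(signatures$W), signatures$W,
                        check.names = FALSE), w_path)
  .write_tsv(data.frame(signature = rownames(signatures$H), signatures$H,
                        check.names = FALSE), h_path)
  invisible(c(w_path, h_path))
}
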