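#' Euclidean projection of a vector onto the probability simplex
#'
#' Exact sort-and-threshold projection: the unique point of the simplex
#' closest to \code{v} in Euclidean distance. This is not the same as
#' clamping negatives and renormalizing.
#'
#' @param v numeric vector.
#' @return non-negative vector summing to 1.
#' @export
project_simplex <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u + (1 - css) / seq_along(u) > 0))
  theta <- (1 - css[rho]) / rho
  pmax(v + theta, 0)
}

# One-hot encoding of an integer call matrix (values 0..C-1, NA missing):
# returns n x (S*C) matrix, site-major column blocks, with missing entries 0
# (they are excluded from all least-squares rows via the obs mask).
one_hot_encode <- function(X, n_cat) {
  n <- nrow(X); S <- ncol(X)
  E <- matrix(0, n, S * n_cat)
  for (a in 0:(n_cat - 1L)) {
    idx <- which(X == a, arr.ind = TRUE)
    if (nrow(idx))
      E[cbind(idx[, 1], (idx[, 2] - 1L) * n_cat + a + 1L)] <- 1
  }
  E
}

#' Ancestry estimation by least-squares sparse nonnegative matrix
#' factorization
#'
#' Factorizes the one-hot-encoded genotype matrix X (samples x site
#' categories) as X ~ Q G, where each row of Q holds a sample's ancestry
#' coefficients on the probability simplex and G holds per-cluster
#' genotype-category frequencies. Alternating least squares: G is solved
#' per site over the samples observed there, negatives clamped to zero and
#' category frequencies renormalized per site; Q is solved per sample over
#' its observed sites (optional ridge penalty \code{alpha}) and each row is
#' projected exactly onto the simplex. Missing sites contribute nothing to
#' either solve. Runs \code{iterations} alternations, or stops early when
#' the squared-error loss changes by less than \code{tol}. Deterministic
#' given \code{seed} (Q is initialized from seeded flat-Dirichlet rows).
#'
#' @param X integer matrix samples x sites with calls in 0..(n_cat-1) and NA
#'   for missing (haploid 0/1 by default; 0/1/2 works with
#'   \code{n_cat = 3}), e.g. a \code{\link{build_genotype_matrix}} result.
#' @param K number of ancestral clusters.
#' @param iterations number of alternations (default 100).
#' @param seed RNG seed for the initialization.
#' @param alpha ridge penalty on the Q solve (default 0).
#' @param n_cat number of genotype categories per site (default: inferred
#'   as max call + 1, at least 2).
#' @param tol early-stopping threshold on the loss change.
#' @return list of class \code{"ancestry_result"}: Q (samples x K), G
#'   (K x sites*categories), loss_trajectory, K, seed, iterations_run.
#' @export
snmf_ancestry <- function(X, K, iterations = 100L, seed = 1L, alpha = 0,
                          n_cat = NULL, tol = 1e-8) {
  X <- unclass(X)
  stopifnot(is.matrix(X), K >= 1L, iterations >= 1L)
  n <- nrow(X); S <- ncol(X)
  if (S < 1L) stop("matrix must have at least one site")
  if (K > n) stop("K larger than the number of samples")
  if (is.null(rownames(X))) rownames(X) <- paste0("sample", seq_len(n))
  all_missing <- rowSums(!is.na(X)) == 0L
  if (any(all_missing))
    stop("sample(s) with no data: ",
         paste(rownames(X)[all_missing], collapse = ", "))
  if (is.null(n_cat)) n_cat <- max(2L, max(X, na.rm = TRUE) + 1L)

  E <- one_hot_encode(X, n_cat)
  obs <- !is.na(X)                        # n x S
  # expand per-category observation mask
  obs_cat <- obs[, rep(seq_len(S), each = n_cat), drop = FALSE]

  set.seed(seed)
  Q <- matrix(stats::rgamma(n * K, shape = 1), n, K)
  Q <- Q / rowSums(Q)
  G <- matrix(0, K, S * n_cat)

  # group sites by observation pattern so each pattern is solved once
  pat <- apply(obs, 2, function(v) paste(which(v), collapse = ","))
  site_groups <- split(seq_len(S), pat)
  # group samples by observation pattern for the Q solve
  spat <- apply(obs, 1, function(v) paste(which(v), collapse = ","))
  sample_groups <- split(seq_len(n), spat)

  loss_fn <- function(Q, G) {
    R <- (E - Q %*% G) * obs_cat
    sum(R * R)
  }
  loss <- numeric(0)
  prev <- Inf
  it_run <- 0L
  for (it in seq_len(iterations)) {
    # --- G update ---
    for (g in site_groups) {
      rows <- which(obs[, g[1]])
      cols <- as.vector(outer(seq_len(n_cat), (g - 1L) * n_cat, `+`))
      Qo <- Q[rows, , drop = FALSE]
      A <- crossprod(Qo)
      B <- crossprod(Qo, E[rows, cols, drop = FALSE])
      Gg <- tryCatch(solve(A, B),
                     error = function(e) solve(A + diag(1e-8, K), B))
      Gg[Gg < 0] <- 0
      # renormalize category frequencies per site within each cluster
      for (k in seq_len(K)) {
        gk <- matrix(Gg[k, ], nrow = n_cat)
        cs <- colSums(gk)
        gk[, cs > 0] <- sweep(gk[, cs > 0, drop = FALSE], 2, cs[cs > 0], "/")
        gk[, cs == 0] <- 1 / n_cat
        Gg[k, ] <- as.vector(gk)
      }
      G[, cols] <- Gg
    }
    # --- Q update ---
    for (sg in sample_groups) {
      sites_i <- which(obs[sg[1], ])
      cols <- as.vector(outer(seq_len(n_cat), (sites_i - 1L) * n_cat, `+`))
      Gi <- G[, cols, drop = FALSE]
      M <- Gi %*% t(Gi) + diag(alpha, K)
      for (i in sg) {
        b <- Gi %*% E[i, cols]
        q <- tryCatch(solve(M, b),
                      error = function(e) solve(M + diag(1e-8, K), b))
        Q[i, ] <- project_simplex(as.vector(q))
      }
    }
    stopifnot(all(Q >= 0), all(abs(rowSums(Q) - 1) < 1e-9))
    cur <- loss_fn(Q, G)
    loss <- c(loss, cur)
    it_run <- it
    if (abs(prev - cur) < tol) break
    prev <- cur
  }
  rownames(Q) <- rownames(X)
  structure(list(Q = Q, G = G, loss_trajectory = loss, K = K,
                 seed = seed, n_cat = n_cat, iterations_run = it_run),
            class = "ancestry_result")
}

#' @export
print.ancestry_result <- function(x, ...) {
  cat(sprintf("ancestry_result: %d samples, K = %d, %d iteration(s), final loss %.6g\n",
              nrow(x$Q), x$K, x$iterations_run,
              utils::tail(x$loss_trajectory, 1)))
  invisible(x)
}

all_permutations <- function(k) {
  if (k == 1L) return(list(1L))
  out <- list()
  for (p in all_permutations(k - 1L))
    for (pos in seq_len(k))
      out[[length(out) + 1L]] <- append(p, k, after = pos - 1L)
  out
}

#' Resolve label switching against a reference Q matrix
#'
#' Permutes the columns of \code{Q_est} to minimize the total absolute
#' difference from \code{Q_truth}, exhaustively over all K! permutations.
#'
#' @param Q_est,Q_truth matrices of identical dimensions (K <= 8).
#' @return \code{Q_est} with permuted columns; the permutation applied is
#'   attached as attribute \code{perm}.
#' @export
align_labels <- function(Q_est, Q_truth) {
  stopifnot(all(dim(Q_est) == dim(Q_truth)))
  K <- ncol(Q_est)
  if (K > 8L) stop("exhaustive label alignment supports K <= 8")
  best <- NULL
  best_err <- Inf
  for (p in all_permutations(K)) {
    err <- sum(abs(Q_est[, p, drop = FALSE] - Q_truth))
    if (err < best_err) { best_err <- err; best <- p }
  }
  structure(Q_est[, best, drop = FALSE], perm = best)
}

#' Cluster-membership barplot of ancestry coefficients
#'
#' @param result an \code{\link{snmf_ancestry}} result (or a Q matrix).
#' @param ... passed to \code{\link[graphics]{barplot}}.
#' @export
plot_ancestry <- function(result, ...) {
  Q <- if (inherits(result, "ancestry_result")) result$Q else result
  graphics::barplot(t(Q), col = grDevices::hcl.colors(ncol(Q), "Dark 3"),
                    border = NA, space = 0, las = 2,
                    ylab = "ancestry coefficient", ...)
  invisible(Q)
}
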