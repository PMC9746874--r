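# Chunked gamma-Poisson sampling: draws NB counts for blocks of cells and
# assembles one sparse matrix, keeping peak memory proportional to the
# chunk, not the dataset.
.nb_counts_sparse <- function(gene_means, cell_factors, size,
                              gene_ids, cell_ids, chunk = 500L,
                              dropout_mid = NULL, dropout_shape = -1) {
  G <- length(gene_means)
  n <- length(cell_factors)
  ii <- list(); jj <- list(); xx <- list()
  b <- 1L
  for (start in seq.int(1L, n, by = chunk)) {
    end <- min(start + chunk - 1L, n)
    mu <- outer(gene_means, cell_factors[start:end])
    cnt <- rnbinom(length(mu), mu = mu, size = size)
    if (!is.null(dropout_mid)) {
      pkeep <- 1 - 1 / (1 + exp(-dropout_shape * (log(mu) - dropout_mid)))
      cnt <- cnt * rbinom(length(mu), 1L, pkeep)
    }
    pos <- which(cnt > 0L)
    ii[[b]] <- (pos - 1L) %% G + 1L
    jj[[b]] <- (pos - 1L) %/% G + start
    xx[[b]] <- cnt[pos]
    b <- b + 1L
  }
  Matrix::sparseMatrix(
    i = unlist(ii), j = unlist(jj), x = unlist(xx),
    dims = c(G, n), dimnames = list(gene_ids, cell_ids)
  )
}

.pad_ids <- function(prefix, n) sprintf("%s%0*d", prefix, nchar(n), seq_len(n))

#' Splat-style artificial scRNA-seq simulator with known DE genes
#'
#' Generates a two-group gamma-Poisson (negative binomial) count matrix in
#' the spirit of splat-type simulators: per-gene base means drawn from a
#' gamma distribution, log-normal per-cell library-size factors, a
#' BCV-derived common dispersion, and, for the designated DE genes,
#' log-normal multiplicative fold changes applied to group 2 with random
#' up/down direction. Cell means are renormalised within each group so
#' that a cell's expected total equals its library size. An optional
#' logistic-in-log-mean dropout layer can zero counts on top of the NB
#' sampling.
#'
#' `de_factor` is the log-normal location of the DE multipliers: 0 (with
#' `de_factor_scale = 0`) makes every multiplier exactly 1 and the
#' generator an exact null.
#'
#' @param n_genes_nonde,n_genes_de Numbers of non-DE and DE genes
#'   (defaults 10000 and 1000).
#' @param n_cells Total number of cells, split into two equal groups (must
#'   be even).
#' @param de_factor,de_factor_scale Location and sd of the log-normal DE
#'   multiplier (defaults 0.5 and 0.4).
#' @param mean_shape,mean_rate Gamma hyperparameters of gene base means
#'   (defaults 0.6 and 0.3).
#' @param libsize_loc,libsize_scale Log-normal library-size hyperparameters
#'   (defaults `log(2000)` and 0.3).
#' @param bcv Biological coefficient of variation; NB dispersion is
#'   `bcv^2` (default 0.2).
#' @param dropout_mid,dropout_shape Optional logistic dropout: midpoint on
#'   the log-mean scale and (negative) slope. `dropout_mid = NULL`
#'   (default) disables dropout.
#' @param seed RNG seed; output is deterministic given the seed.
#' @return An object of class `sim_dataset`: list with `counts` (sparse
#'   genes x cells), `groups` (named 1/2 labels, first half group 1),
#'   `truth_de` (designated DE gene ids), `multipliers` (per-gene group-2 /
#'   group-1 expected fold change; exactly 1 for non-DE genes).
#' @examples
#' sim <- simulate_splat_like(n_genes_nonde = 500, n_genes_de = 50,
#'                            n_cells = 100, seed = 1)
#' mean(sim$counts == 0)
#' @export
simulate_splat_like <- function(n_genes_nonde = 10000, n_genes_de = 1000,
                                n_cells, de_factor = 0.5,
                                de_factor_scale = 0.4,
                                mean_shape = 0.6, mean_rate = 0.3,
                                libsize_loc = log(2000), libsize_scale = 0.3,
                                bcv = 0.2, dropout_mid = NULL,
                                dropout_shape = -1, seed = NULL) {
  stopifnot(n_genes_nonde >= 1, n_genes_de >= 0, n_cells >= 2,
            de_factor >= 0, de_factor_scale >= 0, bcv > 0,
            mean_shape > 0, mean_rate > 0, libsize_scale >= 0)
  if (n_cells %% 2 != 0) stop("n_cells must be even (two equal groups)")
  if (!is.null(seed)) set.seed(seed)

  G <- n_genes_nonde + n_genes_de
  gene_ids <- .pad_ids("gene", G)
  cell_ids <- .pad_ids("cell", n_cells)

  base <- rgamma(G, shape = mean_shape, rate = mean_rate)
  de_idx <- sample.int(G, n_genes_de)
  mult <- rep(1, G)
  if (n_genes_de > 0) {
    f <- rlnorm(n_genes_de, meanlog = de_factor, sdlog = de_factor_scale)
    dirn <- sample(c(1, -1), n_genes_de, replace = TRUE)
    mult[de_idx] <- f^dirn
  }

  half <- n_cells %/% 2L
  libsize <- rlnorm(n_cells, meanlog = libsize_loc, sdlog = libsize_scale)
  w1 <- base / sum(base)
  m2 <- base * mult
  w2 <- m2 / sum(m2)
  size <- 1 / bcv^2

  c1 <- .nb_counts_sparse(w1, libsize[seq_len(half)], size,
                          gene_ids, cell_ids[seq_len(half)],
                          dropout_mid = dropout_mid,
                          dropout_shape = dropout_shape)
  c2 <- .nb_counts_sparse(w2, libsize[(half + 1L):n_cells], size,
                          gene_ids, cell_ids[(half + 1L):n_cells],
                          dropout_mid = dropout_mid,
                          dropout_shape = dropout_shape)
  counts <- methods::cbind2(c1, c2)

  groups <- rep(c(1L, 2L), each = half)
  names(groups) <- cell_ids
  structure(
    list(counts = counts, groups = groups,
         truth_de = gene_ids[sort(de_idx)],
         multipliers = mult),
    class = "sim_dataset"
  )
}

#' Synthetic UMI-like source matrix with exchangeable cells
#'
#' Generates a sparse count matrix that mimics a filtered droplet UMI
#' dataset: heavy-tailed gamma gene means with a detection floor (every
#' retained gene is expected in at least ~1% of cells, as after standard
#' expression filtering), negative binomial counts with mild
#' overdispersion, and log-normal library-size variation. Gene means are
#' rescaled numerically so the overall zero fraction matches
#' `sparsity_target`. Cells are exchangeable (no group structure), which
#' makes the matrix a valid null source for [make_semisim()].
#'
#' @param n_genes,n_cells Matrix dimensions.
#' @param sparsity_target Overall zero fraction to aim for, in (0.5, 0.99);
#'   achieved within about +/- 0.05.
#' @param seed RNG seed.
#' @param mean_shape Gamma shape of the (unscaled) gene means (default
#'   0.4, heavy-tailed).
#' @param dispersion NB dispersion (1/size) of counts across cells
#'   (default 0.3, mild UMI-scale overdispersion).
#' @param libsize_scale Log-normal sd of per-cell library factors (default
#'   0.25); factors are normalised to mean 1.
#' @return A sparse genes x cells `dgCMatrix` with ids as dimnames.
#' @export
simulate_pbmc_like_source <- function(n_genes, n_cells,
                                      sparsity_target = 0.9, seed = NULL,
                                      mean_shape = 0.4, dispersion = 0.3,
                                      libsize_scale = 0.25) {
  stopifnot(n_genes >= 1, n_cells >= 1)
  if (sparsity_target <= 0.5 || sparsity_target >= 0.99)
    stop("sparsity_target must lie in (0.5, 0.99)")
  if (!is.null(seed)) set.seed(seed)

  lam0 <- rgamma(n_genes, shape = mean_shape, rate = 1)
  size <- 1 / dispersion
  lam_floor <- 0.01  # ~1% expected detection, emulating expression filtering
  zero_frac <- function(scale) {
    lam <- pmax(scale * lam0, lam_floor)
    mean((size / (size + lam))^size)
  }
  lo <- 1e-8; hi <- 1e6
  if (zero_frac(lo) < sparsity_target || zero_frac(hi) > sparsity_target)
    stop("sparsity_target ", sparsity_target,
         " is unreachable under the generator constraints")
  scale <- uniroot(function(s) zero_frac(s) - sparsity_target,
                   lower = lo, upper = hi, tol = 1e-10)$root
  lam <- pmax(scale * lam0, lam_floor)

  cf <- rlnorm(n_cells, meanlog = 0, sdlog = libsize_scale)
  cf <- cf / exp(libsize_scale^2 / 2)

  .nb_counts_sparse(lam, cf, size,
                    .pad_ids("gene", n_genes), .pad_ids("cell", n_cells))
}
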