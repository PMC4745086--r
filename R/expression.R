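# FPKM quantification and no-replicate negative-binomial differential
# expression between two single-sample conditions.
#
# With one library per condition there is no within-condition replication,
# so the dispersion is estimated by treating the two conditions as if they
# were replicates ("blind" pooling). Truly differential genes inflate this
# estimate, making the resulting exact test conservative — the standard
# trade-off for no-replicate designs.

#' Fragments per kilobase of transcript per million mapped fragments
#'
#' `FPKM = C * 1e9 / (N * L)` where `C` is the fragment count uniquely
#' aligned to the gene, `N` the total number of uniquely aligned fragments
#' in the library and `L` the gene length in bases.
#'
#' @param C Fragment count(s) for the gene(s); non-negative.
#' @param N_total Total mapped fragments in the library; >= 1.
#' @param L Gene length(s) in bases; >= 1.
#' @return Numeric vector of FPKM values.
#' @examples
#' compute_fpkm(1000, 1e6, 1000)  # 1000
#' @export
compute_fpkm <- function(C, N_total, L) {
  if (any(N_total < 1)) stop_validation("compute_fpkm: N_total must be >= 1")
  if (any(L < 1)) stop_validation("compute_fpkm: L must be >= 1")
  if (any(C < 0)) stop_validation("compute_fpkm: counts must be >= 0")
  C * 1e9 / (N_total * L)
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization constants: for each sample, the median over
#' genes (restricted to genes with positive counts in every sample) of the
#' ratio of the gene's count to its across-sample geometric mean.
#'
#' @param counts A numeric matrix or data frame of non-negative counts,
#'   genes in rows, samples in columns. A `gene_id` column, if present, is
#'   ignored.
#' @return Named numeric vector of positive size factors, one per sample.
#' @export
size_factors <- function(counts) {
  m <- as_count_matrix(counts)
  pos <- rowSums(m > 0) == ncol(m)
  if (!any(pos)) {
    stop_validation("size_factors: no gene has positive counts in every sample")
  }
  logm <- log(m[pos, , drop = FALSE])
  log_geo <- rowMeans(logm)
  apply(logm, 2, function(col) exp(median(col - log_geo)))
}

as_count_matrix <- function(counts) {
  if (is.data.frame(counts)) {
    keep <- !vapply(counts, is.character, TRUE)
    m <- as.matrix(counts[, keep, drop = FALSE])
    id_col <- which(vapply(counts, is.character, TRUE))
    if (length(id_col)) rownames(m) <- counts[[id_col[1]]]
  } else {
    m <- as.matrix(counts)
  }
  storage.mode(m) <- "double"
  if (any(m < 0) || anyNA(m)) {
    stop_validation("counts must be non-negative and complete")
  }
  m
}

#' Fit a mean-dispersion relation from a no-replicate two-sample design
#'
#' Per-gene method-of-moments dispersions are computed treating the two
#' conditions as replicates; the relation `alpha(mu) = a0/mu + a1` is then
#' fitted by ordinary least squares of the raw dispersion on `1/mu`, and
#' predictions are floored at `alpha_min`. Only genes with normalized mean
#' at or above `min_mean` enter the fit.
#'
#' @inheritParams size_factors
#' @param factors Per-sample size factors, e.g. from [size_factors()].
#' @param alpha_min Dispersion floor (default `1e-8`).
#' @param min_mean Minimum normalized mean for a gene to enter the fit
#'   (default 1).
#' @return An object of class `dispersion_model` with elements `a0`, `a1`,
#'   `alpha_min` and `n_genes_used`. Use [predict_dispersion()] to evaluate.
#' @export
fit_dispersion <- function(counts, factors, alpha_min = 1e-8, min_mean = 1) {
  m <- as_count_matrix(counts)
  if (length(factors) != ncol(m) || any(factors <= 0)) {
    stop_validation("fit_dispersion: need one positive size factor per sample")
  }
  norm <- sweep(m, 2, factors, "/")
  mu <- rowMeans(norm)
  w <- apply(norm, 1, var)
  z <- mu * mean(1 / factors)          # shot-noise component of the variance
  raw <- (w - z) / mu^2
  use <- is.finite(raw) & mu >= min_mean
  if (sum(use) < 10L) {
    stop_validation("fit_dispersion: fewer than 10 usable genes")
  }
  fit <- lm(raw[use] ~ I(1 / mu[use]))
  structure(
    list(a0 = unname(coef(fit)[2]), a1 = unname(coef(fit)[1]),
         alpha_min = alpha_min, n_genes_used = sum(use)),
    class = "dispersion_model"
  )
}

#' Evaluate a fitted mean-dispersion relation
#'
#' @param model A `dispersion_model` from [fit_dispersion()].
#' @param mu Positive normalized mean(s).
#' @return Dispersion value(s), floored at the model's `alpha_min`.
#' @export
predict_dispersion <- function(model, mu) {
  stopifnot(inherits(model, "dispersion_model"))
  pmax(model$a0 / mu + model$a1, model$alpha_min)
}

#' @export
print.dispersion_model <- function(x, ...) {
  cat("Mean-dispersion model: alpha(mu) = a0/mu + a1\n")
  cat(sprintf("  a0 = %.6g, a1 = %.6g (floor %.1g; %d genes used)\n",
              x$a0, x$a1, x$alpha_min, x$n_genes_used))
  invisible(x)
}

#' @export
tidy.dispersion_model <- function(x, ...) {
  tibble::tibble(term = c("a0", "a1"), estimate = c(x$a0, x$a1))
}

#' @export
glance.dispersion_model <- function(x, ...) {
  tibble::tibble(a0 = x$a0, a1 = x$a1, alpha_min = x$alpha_min,
                 n_genes_used = x$n_genes_used)
}

#' Two-condition negative-binomial exact test
#'
#' Conditional on the total `kA + kB`, sums the joint NB probabilities of
#' all count splits `(a, b)` with `a + b = kA + kB` that are no more likely
#' than the observed split, and divides by the total probability of the
#' support (two-sided exact test). Both conditions share the dispersion
#' evaluated at the pooled normalized mean.
#'
#' @param kA,kB Observed counts in conditions A and B.
#' @param sA,sB Positive size factors of the two samples.
#' @param model A `dispersion_model` from [fit_dispersion()].
#' @return A p-value in (0, 1]; `kA + kB = 0` returns 1 by convention.
#' @export
nb_exact_test <- function(kA, kB, sA, sB, model) {
  if (sA <= 0 || sB <= 0) stop_validation("nb_exact_test: size factors must be > 0")
  if (kA < 0 || kB < 0) stop_validation("nb_exact_test: counts must be >= 0")
  S <- kA + kB
  if (S == 0) return(1)
  q0 <- (kA / sA + kB / sB) / 2
  alpha <- predict_dispersion(model, q0)
  size <- 1 / alpha
  muA <- sA * q0
  muB <- sB * q0
  # restrict the support to where the probability mass lives; the neglected
  # tails carry < 1e-12 of the total mass
  if (S > 50000) {
    loA <- stats::qnbinom(1e-13, size = size, mu = muA)
    hiA <- stats::qnbinom(1e-13, size = size, mu = muA, lower.tail = FALSE)
    loB <- stats::qnbinom(1e-13, size = size, mu = muB)
    hiB <- stats::qnbinom(1e-13, size = size, mu = muB, lower.tail = FALSE)
    a <- max(0, min(loA, S - hiB)):min(S, max(hiA, S - loB))
    a <- sort(unique(c(a, kA)))
  } else {
    a <- 0:S
  }
  logp <- dnbinom(a, size = size, mu = muA, log = TRUE) +
    dnbinom(S - a, size = size, mu = muB, log = TRUE)
  obs <- logp[match(kA, a)]
  keep <- logp <= obs + 1e-7
  p <- exp(logsumexp(logp[keep]) - logsumexp(logp))
  min(max(p, .Machine$double.xmin), 1)
}

#' Call differentially expressed genes between two single samples
#'
#' Runs the full no-replicate pipeline: median-of-ratios size factors,
#' blind mean-dispersion fit, per-gene NB exact test, Benjamini-Hochberg
#' correction, and up/down/unchanged calls at the supplied thresholds. The
#' log2 fold change is computed on size-factor-normalized counts with a
#' pseudo-count of 0.5 in each condition, which keeps one-sided zeros
#' finite while preserving direction.
#'
#' @param counts A data frame with a `gene_id` character column and exactly
#'   two count columns (condition A then condition B), or a 2-column count
#'   matrix with gene rownames.
#' @param q_threshold FDR threshold for a call (default 0.05).
#' @param lfc_threshold Genes must satisfy `|log2fc| > lfc_threshold`
#'   (strict) to be called (default 1).
#' @param alpha_min Dispersion floor passed to [fit_dispersion()].
#' @return A tibble with columns `gene_id`, `baseMeanA`, `baseMeanB`,
#'   `log2fc`, `pvalue`, `qvalue`, `call` (factor with levels `down`,
#'   `unchanged`, `up`).
#' @examples
#' sim <- simulate_nb_counts(60, seed = 1, n_de = 6, lfc = 3,
#'                           mean_range = c(200, 2000))
#' de <- call_de(sim$counts)
#' table(de$call)
#' @export
call_de <- function(counts, q_threshold = 0.05, lfc_threshold = 1,
                    alpha_min = 1e-8) {
  m <- as_count_matrix(counts)
  if (ncol(m) != 2L) stop_validation("call_de: expected exactly two samples")
  gene_id <- rownames(m)
  if (is.null(gene_id)) gene_id <- paste0("gene", seq_len(nrow(m)))
  sf <- size_factors(m)
  model <- fit_dispersion(m, sf, alpha_min = alpha_min)
  kA <- m[, 1]
  kB <- m[, 2]
  pvals <- vapply(seq_len(nrow(m)), function(i) {
    nb_exact_test(kA[i], kB[i], sf[1], sf[2], model)
  }, 1.0)
  qvals <- benjamini_hochberg(pvals)
  nA <- kA / sf[1]
  nB <- kB / sf[2]
  lfc <- log2((nB + 0.5) / (nA + 0.5))
  call <- ifelse(qvals < q_threshold & abs(lfc) > lfc_threshold,
                 ifelse(lfc > 0, "up", "down"), "unchanged")
  tibble::tibble(
    gene_id = gene_id,
    baseMeanA = nA,
    baseMeanB = nB,
    log2fc = lfc,
    pvalue = pvals,
    qvalue = qvals,
    call = factor(call, levels = c("down", "unchanged", "up"))
  )
}

#' Write a differential-expression table as TSV
#'
#' @param de A tibble from [call_de()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(de, path) {
  readr::write_tsv(de, path)
  invisible(path)
}

#' Read a count table
#'
#' First column `gene_id`, one column per sample, header row required.
#'
#' @param path Path to a TSV count table.
#' @return A tibble with a `gene_id` column and numeric sample columns.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop_validation(paste0("file not found: ", path))
  out <- readr::read_tsv(path, show_col_types = FALSE)
  if (ncol(out) < 2L || names(out)[1] != "gene_id") {
    stop_parse("count table must have a 'gene_id' first column plus samples")
  }
  out
}
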