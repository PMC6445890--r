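#' @include AllClasses.R
NULL

#' Study conditions for the synthetic drug-response generator
#'
#' Defaults emulate the structure of public cell-line drug screens at a
#' size suitable for simulation studies: 200 cell lines; 300 expression,
#' 300 CNA and 100 SNV features; 5 informative features per kind, each
#' contributing one noise-standard-deviation of effect to the latent
#' IC50; correlated blocks of 3 at r = 0.98 among the real-valued
#' features (work for the 0.95 correlation pruning); missing values in
#' IC50/CNA/SNV but never in expression.
#'
#' @param n_cells number of cell lines.
#' @param n_expression,n_cna,n_snv feature counts per kind (0 omits a
#'   kind).
#' @param n_informative informative features per (non-empty) kind.
#' @param effect_size coefficient of each standardised informative
#'   feature in the latent IC50, in units of the noise sd.
#' @param noise_sd sd of the additive Gaussian noise on the latent IC50.
#' @param block_size,block_cor size of and within-block correlation of
#'   the correlated feature blocks (block_size 1 gives independent
#'   features).
#' @param missing_ic50,missing_cna,missing_snv completely-at-random
#'   missingness rates.
#' @param seed generator seed.
#' @return a validated \linkS4class{SyntheticConfig}.
#' @export
syntheticConfig <- function(n_cells = 200L, n_expression = 300L,
                            n_cna = 300L, n_snv = 100L,
                            n_informative = 5L, effect_size = 1.0,
                            noise_sd = 1.0, block_size = 3L,
                            block_cor = 0.98, missing_ic50 = 0.1,
                            missing_cna = 0.05, missing_snv = 0.05,
                            seed = 1L) {
  new("SyntheticConfig", n_cells = as.integer(n_cells),
      n_expression = as.integer(n_expression), n_cna = as.integer(n_cna),
      n_snv = as.integer(n_snv), n_informative = as.integer(n_informative),
      effect_size = effect_size, noise_sd = noise_sd,
      block_size = as.integer(block_size), block_cor = block_cor,
      missing_ic50 = missing_ic50, missing_cna = missing_cna,
      missing_snv = missing_snv, seed = as.integer(seed))
}

.block_gaussian <- function(n, p, block_size, rho, prefix) {
  if (block_size <= 1L || rho == 0) {
    m <- matrix(rnorm(n * p), n, p)
  } else {
    m <- matrix(0, n, p)
    j <- 1L
    while (j <= p) {
      b <- min(block_size, p - j + 1L)
      f <- rnorm(n)
      eps <- matrix(rnorm(n * b), n, b)
      m[, j:(j + b - 1L)] <- sqrt(rho) * f + sqrt(1 - rho) * eps
      j <- j + b
    }
  }
  colnames(m) <- paste0(prefix, seq_len(p))
  m
}

.standardize_cols <- function(m) {
  s <- apply(m, 2L, sd)
  s[s == 0 | !is.finite(s)] <- 1
  sweep(sweep(m, 2L, colMeans(m)), 2L, s, "/")
}

.inject_mcar <- function(m, rate) {
  if (rate <= 0) return(m)
  mask <- matrix(runif(length(m)) < rate, nrow(m), ncol(m))
  m[mask] <- NA_real_
  m
}

#' Generate a synthetic drug-response dataset with planted signal
#'
#' Draws block-correlated Gaussian expression and CNA tables, Bernoulli
#' SNV calls with per-feature prevalence in [0.05, 0.4], and a latent
#' IC50 equal to \code{effect_size} times the sum of the standardised
#' informative features plus Gaussian noise. Missing values are injected
#' completely at random into IC50/CNA/SNV (never expression). The ground
#' truth lists the informative feature ids and their coefficients.
#'
#' @param config a \linkS4class{SyntheticConfig}.
#' @return list with \code{features} (named list of
#'   \linkS4class{FeatureMatrix}), \code{response} (a one-drug
#'   \linkS4class{ResponseTable}, drug id \code{"drug1"}) and
#'   \code{truth} (informative ids, coefficients, seed).
#' @examples
#' ds <- generateDataset(syntheticConfig(n_cells = 50, n_expression = 20,
#'                                       n_cna = 0, n_snv = 0,
#'                                       n_informative = 2, seed = 3))
#' ds$truth$informative
#' @export
generateDataset <- function(config) {
  stopifnot(is(config, "SyntheticConfig"))
  validObject(config)
  .with_seed(config@seed, {
    n <- config@n_cells
    cells <- sprintf("CL%04d", seq_len(n))

    mats <- list()
    if (config@n_expression > 0L)
      mats$expression <- .block_gaussian(n, config@n_expression,
                                         config@block_size,
                                         config@block_cor, "rna_g")
    if (config@n_cna > 0L)
      mats$cna <- .block_gaussian(n, config@n_cna, config@block_size,
                                  config@block_cor, "cna_g")
    if (config@n_snv > 0L) {
      prev <- runif(config@n_snv, 0.05, 0.4)
      snv <- vapply(prev, function(p) rbinom(n, 1L, p), numeric(n))
      colnames(snv) <- paste0("snv_g", seq_len(config@n_snv))
      mats$snv <- snv
    }
    for (k in names(mats)) rownames(mats[[k]]) <- cells

    informative <- lapply(mats, function(m)
      sort(sample(colnames(m), min(config@n_informative, ncol(m)))))
    latent <- rnorm(n, 0, config@noise_sd)
    coefs <- list()
    for (k in names(mats)) {
      if (!length(informative[[k]])) next
      z <- .standardize_cols(mats[[k]][, informative[[k]], drop = FALSE])
      latent <- latent + config@effect_size * rowSums(z)
      coefs[[k]] <- setNames(rep(config@effect_size,
                                 length(informative[[k]])),
                             informative[[k]])
    }

    ic50 <- matrix(latent, 1L, n, dimnames = list("drug1", cells))
    ic50 <- .inject_mcar(ic50, config@missing_ic50)
    if (!is.null(mats$cna))
      mats$cna <- .inject_mcar(mats$cna, config@missing_cna)
    if (!is.null(mats$snv))
      mats$snv <- .inject_mcar(mats$snv, config@missing_snv)

    features <- lapply(names(mats), function(k) FeatureMatrix(mats[[k]], k))
    names(features) <- names(mats)
    list(features = features,
         response = ResponseTable(ic50),
         truth = list(informative = informative, coefficients = coefs,
                      effect_size = config@effect_size,
                      noise_sd = config@noise_sd, seed = config@seed,
                      threshold = NULL))
  })
}

#' Impose class imbalance via an external labelling threshold
#'
#' The median split is balanced by construction, so imbalance is created
#' by fixing an external IC50 threshold: the empirical
#' \code{1 - target_fraction} quantile of the observed IC50 values, below
#' which a cell line is sensitive. Labelling with this threshold (stored
#' in \code{truth$threshold}) makes the non-sensitive fraction
#' approximate \code{target_fraction}, exercising the EasyEnsemble path.
#'
#' @param dataset a dataset from \code{\link{generateDataset}}.
#' @param target_fraction desired non-sensitive fraction, in (0.5, 1).
#' @return the dataset with \code{truth$threshold} set.
#' @export
makeImbalanced <- function(dataset, target_fraction) {
  if (!is.numeric(target_fraction) || length(target_fraction) != 1L ||
      target_fraction <= 0.5 || target_fraction >= 1)
    stop("target_fraction must lie in (0.5, 1)", call. = FALSE)
  ic <- ic50Values(dataset$response)[1L, ]
  obs <- ic[!is.na(ic)]
  thr <- unname(quantile(obs, 1 - target_fraction))
  achieved <- mean(obs >= thr)
  if (abs(achieved - target_fraction) > 0.1)
    stop(sprintf("target fraction %.2f unattainable (achieved %.2f)",
                 target_fraction, achieved), call. = FALSE)
  dataset$truth$threshold <- thr
  dataset
}
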