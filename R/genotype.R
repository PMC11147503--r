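GENO_CLASSES <- c("hom_mut", "het_mut_silent", "hom_silent",
                  "mut_wt", "silent_wt", "unedited")

#' Genotype distribution under the donor-mixture model
#'
#' Each allele of a diploid clone is independently edited with probability
#' `h`; an edited allele carries the mutant donor with probability `p` and
#' the silent donor otherwise. The resulting class probabilities are
#' `hom_mut = h^2 p^2`, `het_mut_silent = 2 h^2 p (1-p)`,
#' `hom_silent = h^2 (1-p)^2`, `mut_wt = 2 h (1-h) p`,
#' `silent_wt = 2 h (1-h) (1-p)`, `unedited = (1-h)^2`. A conditional view
#' renormalised over classes with at least one edited allele is included.
#'
#' @param p Fraction of mutant donor among delivered donors, in `[0, 1]`.
#' @param h Per-allele HDR probability, in `[0, 1]`.
#' @return A `genotype_distribution`: `probs` (named, sums to 1),
#'   `conditional_edited` (renormalised over the five edited classes),
#'   `conditional_biallelic` (over the three biallelic-edited classes),
#'   and the parameters.
#' @export
genotype_distribution <- function(p, h) {
  stopifnot(p >= 0, p <= 1, h >= 0, h <= 1)
  probs <- c(
    hom_mut = h^2 * p^2,
    het_mut_silent = 2 * h^2 * p * (1 - p),
    hom_silent = h^2 * (1 - p)^2,
    mut_wt = 2 * h * (1 - h) * p,
    silent_wt = 2 * h * (1 - h) * (1 - p),
    unedited = (1 - h)^2)
  edited <- probs[setdiff(GENO_CLASSES, "unedited")]
  biall <- probs[c("hom_mut", "het_mut_silent", "hom_silent")]
  structure(list(
    probs = probs,
    conditional_edited = if (sum(edited) > 0) edited / sum(edited)
                         else edited * NA_real_,
    conditional_biallelic = if (sum(biall) > 0) biall / sum(biall)
                            else biall * NA_real_,
    p = p, h = h), class = "genotype_distribution")
}

#' Expected bulk mutant allele frequency
#'
#' The bulk variant allele frequency is `h * p`: linear in the mutant donor
#' proportion with slope `h`, which is what makes zygosity tunable by donor
#' mixing.
#'
#' @inheritParams genotype_distribution
#' @return `h * p`.
#' @export
expected_bulk_vaf <- function(p, h) {
  stopifnot(p >= 0, p <= 1, h >= 0, h <= 1)
  h * p
}

geno_loglik <- function(par, counts) {
  p <- par[1]; h <- par[2]
  probs <- genotype_distribution(p, h)$probs[names(counts)]
  probs <- pmax(probs, 1e-300)
  sum(counts * log(probs))
}

#' Fit the donor-mixture model to clone genotype counts
#'
#' Multinomial maximum likelihood. With the full six-class table the MLE is
#' closed-form (each clone contributes 0-2 edited alleles, of which some
#' are mutant): `h_hat` = edited alleles / (2 n), `p_hat` = mutant alleles /
#' edited alleles. With WT-containing classes pooled or missing the fit is
#' by numerical profile likelihood. 95% confidence intervals are profile
#' likelihood in either case.
#'
#' @param counts Named counts over (a subset of) the classes `hom_mut`,
#'   `het_mut_silent`, `hom_silent`, `mut_wt`, `silent_wt`, `unedited`.
#' @param conf Confidence level (default 0.95).
#' @return A `mixture_fit`: `p_hat`, `h_hat`, `ci_p`, `ci_h`, `loglik`,
#'   `boundary` (character vector naming parameters at 0/1), `n_clones`.
#' @export
fit_mixture <- function(counts, conf = 0.95) {
  counts <- counts[names(counts) %in% GENO_CLASSES]
  if (!length(counts) || sum(counts) == 0)
    stop("no clone counts over recognised genotype classes")
  n <- sum(counts)
  full <- setNames(rep(0L, length(GENO_CLASSES)), GENO_CLASSES)
  full[names(counts)] <- counts
  complete <- all(GENO_CLASSES %in% names(counts))
  if (complete) {
    edited_alleles <- 2 * (full["hom_mut"] + full["het_mut_silent"] +
                           full["hom_silent"]) +
      full["mut_wt"] + full["silent_wt"]
    mut_alleles <- 2 * full["hom_mut"] + full["het_mut_silent"] +
      full["mut_wt"]
    h_hat <- unname(edited_alleles / (2 * n))
    p_hat <- if (edited_alleles > 0) unname(mut_alleles / edited_alleles)
             else NA_real_
  } else {
    fit <- optim(c(0.5, 0.5), function(par) -geno_loglik(par, counts),
                 method = "L-BFGS-B", lower = 1e-6, upper = 1 - 1e-6)
    p_hat <- fit$par[1]; h_hat <- fit$par[2]
  }
  obs <- counts
  ll_hat <- geno_loglik(c(ifelse(is.na(p_hat), 0.5, p_hat), h_hat), obs)
  crit <- stats::qchisq(conf, df = 1) / 2
  profile_ci <- function(which_par, hat, other_hat) {
    prof <- function(v) {
      # maximise over the nuisance parameter
      f <- function(u) {
        par <- if (which_par == "p") c(v, u) else c(u, v)
        geno_loglik(par, obs)
      }
      o <- stats::optimize(f, interval = c(0, 1), maximum = TRUE)
      o$objective
    }
    target <- ll_hat - crit
    lo <- if (hat <= 1e-9 || prof(0) >= target) 0 else
      uniroot(function(v) prof(v) - target, c(0, hat), tol = 1e-7)$root
    hi <- if (hat >= 1 - 1e-9 || prof(1) >= target) 1 else
      uniroot(function(v) prof(v) - target, c(hat, 1), tol = 1e-7)$root
    c(lo, hi)
  }
  ci_p <- if (is.na(p_hat)) c(0, 1) else profile_ci("p", p_hat, h_hat)
  ci_h <- profile_ci("h", h_hat, p_hat)
  boundary <- character(0)
  if (!is.na(p_hat) && (p_hat <= 1e-9 || p_hat >= 1 - 1e-9))
    boundary <- c(boundary, "p")
  if (h_hat <= 1e-9 || h_hat >= 1 - 1e-9) boundary <- c(boundary, "h")
  structure(list(p_hat = p_hat, h_hat = h_hat, ci_p = ci_p, ci_h = ci_h,
                 loglik = ll_hat, boundary = boundary, n_clones = n),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf(
    "<mixture_fit> p = %.4f [%.4f, %.4f], h = %.4f [%.4f, %.4f], n = %d%s\n",
    x$p_hat, x$ci_p[1], x$ci_p[2], x$h_hat, x$ci_h[1], x$ci_h[2],
    x$n_clones,
    if (length(x$boundary)) paste0(" [boundary: ",
                                   paste(x$boundary, collapse = ","), "]")
    else ""))
  invisible(x)
}

#' Plan the mutant donor proportion for a desired zygosity outcome
#'
#' Inverts the closed forms of the donor-mixture model: either a desired
#' heterozygous (mutant/silent) fraction among biallelic-edited clones —
#' `2 p (1-p)`, maximal at 0.5 when `p = 0.5` — or a desired bulk variant
#' allele frequency `h * p`.
#'
#' @param target_het Desired conditional het fraction among
#'   biallelic-edited clones (`<= 0.5`), or `NULL`.
#' @param target_vaf Desired bulk mutant allele frequency, or `NULL`
#'   (exactly one of the two must be given).
#' @param h Per-allele HDR probability (needed for `target_vaf`).
#' @return List: `p` (for `target_het` the root `>= 0.5` is returned;
#'   `p_alt` gives the mirror solution), and `predicted`, the full
#'   [genotype_distribution()] at the planned `p`.
#' @export
plan_donor_ratio <- function(target_het = NULL, target_vaf = NULL, h = 1) {
  if (is.null(target_het) == is.null(target_vaf))
    stop("give exactly one of target_het or target_vaf")
  if (!is.null(target_het)) {
    stopifnot(target_het >= 0)
    if (target_het > 0.5)
      stop("unachievable heterozygous fraction ", target_het,
           ": 2p(1-p) has maximum 0.5 at p = 0.5")
    disc <- sqrt(1 - 2 * target_het)
    p <- (1 + disc) / 2
    p_alt <- (1 - disc) / 2
  } else {
    stopifnot(target_vaf >= 0, h > 0)
    if (target_vaf > h)
      stop("unachievable bulk VAF ", target_vaf, ": maximum is h = ", h)
    p <- target_vaf / h
    p_alt <- p
  }
  list(p = p, p_alt = p_alt, predicted = genotype_distribution(p, h))
}
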