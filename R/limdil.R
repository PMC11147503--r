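#' Limiting-dilution frequency estimation (single-hit Poisson model)
#'
#' Under the single-hit model a well seeded with `d` cells is negative with
#' probability `exp(-f d)`. The frequency `f` is estimated per group by a
#' complementary log-log binomial regression of the positive-well fraction
#' on `log(dose)` as offset (the standard limiting-dilution GLM), which at
#' a single dose reduces exactly to the closed form
#' `f_hat = -log(n_negative / n_wells) / d`. Confidence intervals are Wald
#' on `log f`; a likelihood-ratio test compares frequencies across groups.
#'
#' @param wells Data frame with columns `dose` (cells per well), `n_wells`,
#'   `n_negative`, and optionally `group`.
#' @param conf Confidence level (default 0.95).
#' @return An `ld_result`: data frame `estimates` with one row per group
#'   (`group`, `frequency`, `lower`, `upper`, per cell; `per100` columns
#'   scaled by 100), and `p_group` — the LRT p-value for equality of
#'   frequencies across groups (`NA` with a single group). All-negative
#'   groups give `frequency = 0` with a one-sided upper bound; all-positive
#'   groups give `Inf`, flagged.
#' @export
ld_frequency <- function(wells, conf = 0.95) {
  stopifnot(all(c("dose", "n_wells", "n_negative") %in% names(wells)))
  if (!"group" %in% names(wells)) wells$group <- "all"
  stopifnot(all(wells$dose > 0), all(wells$n_negative >= 0),
            all(wells$n_negative <= wells$n_wells))
  z <- qnorm(1 - (1 - conf) / 2)
  fit_group <- function(w) {
    n_pos <- w$n_wells - w$n_negative
    if (sum(n_pos) == 0L) {
      # all negative: f_hat = 0; one-sided upper bound from the exact
      # binomial lower limit on P(negative) at the total cell dose
      tot_cells <- sum(w$dose * w$n_wells)
      upper <- -log((1 - conf)) / tot_cells
      return(list(frequency = 0, lower = 0, upper = upper, flag = "all_negative"))
    }
    if (sum(w$n_negative) == 0L) {
      tot_cells <- sum(w$dose * w$n_wells)
      lower <- -log(1 - (1 - conf)^(1 / sum(w$n_wells))) / max(w$dose)
      return(list(frequency = Inf, lower = lower, upper = Inf,
                  flag = "all_positive"))
    }
    fit <- glm(cbind(n_pos, w$n_negative) ~ 1 + offset(log(w$dose)),
               family = binomial(link = "cloglog"),
               control = list(epsilon = 1e-12, maxit = 100))
    logf <- unname(coef(fit)[1])
    se <- sqrt(vcov(fit)[1, 1])
    list(frequency = exp(logf), lower = exp(logf - z * se),
         upper = exp(logf + z * se), flag = "", fit = fit)
  }
  groups <- unique(wells$group)
  est <- do.call(rbind, lapply(groups, function(g) {
    r <- fit_group(wells[wells$group == g, , drop = FALSE])
    data.frame(group = g, frequency = r$frequency, lower = r$lower,
               upper = r$upper, per100 = 100 * r$frequency,
               per100_lower = 100 * r$lower, per100_upper = 100 * r$upper,
               flag = r$flag, stringsAsFactors = FALSE)
  }))
  p_group <- NA_real_
  if (length(groups) > 1L && all(est$flag == "")) {
    n_pos <- wells$n_wells - wells$n_negative
    f0 <- glm(cbind(n_pos, wells$n_negative) ~ 1 + offset(log(wells$dose)),
              family = binomial(link = "cloglog"),
              control = list(epsilon = 1e-12, maxit = 100))
    f1 <- glm(cbind(n_pos, wells$n_negative) ~ factor(wells$group) +
                offset(log(wells$dose)),
              family = binomial(link = "cloglog"),
              control = list(epsilon = 1e-12, maxit = 100))
    dev <- f0$deviance - f1$deviance
    p_group <- pchisq(dev, df = length(groups) - 1L, lower.tail = FALSE)
  }
  structure(list(estimates = est, p_group = p_group, conf = conf),
            class = "ld_result")
}

#' @export
print.ld_result <- function(x, ...) {
  cat("<ld_result> single-hit Poisson limiting dilution\n")
  for (i in seq_len(nrow(x$estimates))) {
    e <- x$estimates[i, ]
    cat(sprintf("  %-12s f = %.4f per cell (%.2f per 100; %d%% CI %.2f-%.2f)%s\n",
                e$group, e$frequency, e$per100, round(100 * x$conf),
                e$per100_lower, e$per100_upper,
                if (nzchar(e$flag)) paste0(" [", e$flag, "]") else ""))
  }
  if (!is.na(x$p_group))
    cat(sprintf("  group difference LRT p = %.4g\n", x$p_group))
  invisible(x)
}
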