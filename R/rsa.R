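#' Per-domain relative solvent accessibility summaries
#'
#' Mean and sample standard deviation (n-1 denominator) of the RSA values
#' over each domain interval, alongside the whole-protein mean. RSA values
#' come from an external predictor and are consumed, not computed, here.
#'
#' @param profile an [rsa_profile()].
#' @param domains a list of [domain_annotation()] objects, or a data.frame
#'   with columns `name`, `start`, `end`.
#' @return data.frame with columns `domain`, `n`, `mean`, `sd`,
#'   `protein_mean`.
#' @export
domain_rsa_summary <- function(profile, domains) {
  stopifnot(inherits(profile, "rsa_profile"))
  doms <- as_domain_list(domains)
  L <- length(profile$values)
  pm <- mean(profile$values)
  rows <- lapply(doms, function(d) {
    if (d$end > L) {
      stop(sprintf("domain '%s' end %d exceeds profile length %d",
                   d$name, d$end, L), call. = FALSE)
    }
    v <- profile$values[d$start:d$end]
    data.frame(domain = d$name, n = length(v), mean = mean(v),
               sd = stats::sd(v), protein_mean = pm)
  })
  do.call(rbind, rows)
}

#' Extract the RSA values of one domain
#' @inheritParams domain_rsa_summary
#' @param domain a [domain_annotation()].
#' @return numeric vector.
#' @export
rsa_domain_values <- function(profile, domain) {
  stopifnot(inherits(profile, "rsa_profile"),
            inherits(domain, "domain_annotation"))
  if (domain$end > length(profile$values)) {
    stop(sprintf("domain '%s' end %d exceeds profile length %d",
                 domain$name, domain$end, length(profile$values)),
         call. = FALSE)
  }
  profile$values[domain$start:domain$end]
}

#' Nonparametric comparison of two domains' RSA values
#'
#' Two-sided Mann-Whitney U test ([stats::wilcox.test()]): exact null
#' distribution when the smaller group has at most 8 values and there are no
#' ties, normal approximation with tie correction otherwise. The published
#' comparisons report significance without naming the test; Mann-Whitney is
#' used for consistency with the nonparametric toolkit applied elsewhere in
#' the same study, at alpha 0.01.
#'
#' @param values_a,values_b numeric vectors (non-empty).
#' @param alpha significance level (default 0.01).
#' @param name_a,name_b optional group labels.
#' @return an `rsa_comparison`: list with `group_a`, `group_b`, `n_a`, `n_b`,
#'   `u_statistic` (U of group a), `u_a`, `u_b`, `p_value`, `method`,
#'   `alpha`, `significant`.
#' @export
compare_domains <- function(values_a, values_b, alpha = 0.01,
                            name_a = "a", name_b = "b") {
  if (length(values_a) == 0L || length(values_b) == 0L) {
    stop("compare_domains: empty group", call. = FALSE)
  }
  na <- length(values_a); nb <- length(values_b)
  ties <- anyDuplicated(c(values_a, values_b)) > 0L
  exact <- min(na, nb) <= 8L && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(values_a, values_b, alternative = "two.sided",
                       exact = exact, correct = TRUE))
  u_a <- unname(wt$statistic)
  structure(list(group_a = name_a, group_b = name_b,
                 n_a = na, n_b = nb,
                 u_statistic = u_a, u_a = u_a, u_b = na * nb - u_a,
                 p_value = wt$p.value,
                 method = if (exact) "exact" else "normal-approximation",
                 alpha = alpha,
                 significant = wt$p.value < alpha),
            class = "rsa_comparison")
}

#' @export
print.rsa_comparison <- function(x, ...) {
  cat(sprintf("Mann-Whitney (%s): %s (n=%d) vs %s (n=%d), U=%.1f, p=%.4g%s\n",
              x$method, x$group_a, x$n_a, x$group_b, x$n_b,
              x$u_statistic, x$p_value,
              if (x$significant) sprintf(" (significant at %.2g)", x$alpha) else ""))
  invisible(x)
}

as_domain_list <- function(domains) {
  if (is.data.frame(domains)) {
    lapply(seq_len(nrow(domains)), function(i) {
      domain_annotation(domains$name[i],
                        if ("ref_id" %in% names(domains)) domains$ref_id[i] else NA,
                        domains$start[i], domains$end[i])
    })
  } else if (inherits(domains, "domain_annotation")) {
    list(domains)
  } else {
    stopifnot(all(vapply(domains, inherits, logical(1), "domain_annotation")))
    domains
  }
}
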