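# OARSI-based grouping, descriptive summaries, and knee-clustered bootstrap
# group contrasts over extracted or fitted cartilage properties.

#' Map OARSI grades to OA progression groups
#'
#' Grades 0-1 (intact surface) map to `normal`, 2-3 (fibrillation, minor
#' abrasion) to `moderate`, 4 (fissures, erosion, matrix loss) to `severe`.
#'
#' @param oarsi_grade integer vector of OARSI histopathology grades (0-4).
#' @return Character vector of group labels.
#' @export
assign_group <- function(oarsi_grade) {
  if (any(!is.finite(oarsi_grade)) ||
      any(oarsi_grade != round(oarsi_grade)) ||
      any(oarsi_grade < 0) || any(oarsi_grade > 4))
    stop("OARSI grade must be an integer in 0..4", call. = FALSE)
  c("normal", "normal", "moderate", "moderate", "severe")[oarsi_grade + 1L]
}

# knee-clustered bootstrap of a group-mean difference: resample knees with
# replacement within each group, respecting the within-knee clustering
boot_mean_diff <- function(x1, knee1, x2, knee2, B) {
  k1 <- split(x1, knee1)
  k2 <- split(x2, knee2)
  n1 <- length(k1); n2 <- length(k2)
  vapply(seq_len(B), function(b) {
    s1 <- unlist(k1[sample.int(n1, replace = TRUE)], use.names = FALSE)
    s2 <- unlist(k2[sample.int(n2, replace = TRUE)], use.names = FALSE)
    mean(s2) - mean(s1)
  }, numeric(1))
}

#' Descriptive summaries and group contrasts of cohort properties
#'
#' Per-group (optionally per-compartment) descriptive statistics for each
#' requested parameter, and normal-vs-moderate mean differences with
#' percentile-bootstrap 95\% confidence intervals. The bootstrap resamples
#' knees, not samples, to respect the within-knee clustering. Groups smaller
#' than `min_n_test` (default: the severe group at a 3-specimen cohort) are
#' summarized descriptively but excluded from statistical contrasts.
#'
#' @param data data frame with columns `group`, `knee_id`, optionally
#'   `compartment`, and the parameter columns; e.g. the `samples` table of a
#'   [generate_cohort()] result, or extracted properties joined to it.
#' @param parameters character vector of parameter column names.
#' @param by_compartment logical; additionally stratify summaries by
#'   compartment.
#' @param B bootstrap replicates.
#' @param seed seed for the bootstrap.
#' @param min_n_test minimum group size for inclusion in contrasts.
#' @param conf confidence level.
#' @return Object of class `group_summary`: `summary` (long data frame of
#'   n/mean/SD/median/IQR) and `contrasts` (mean difference moderate - normal
#'   with percentile CI per parameter).
#' @export
summarize_cohort <- function(data, parameters, by_compartment = FALSE,
                             B = 2000, seed = 1L, min_n_test = 5,
                             conf = 0.95) {
  stopifnot(all(c("group", "knee_id") %in% names(data)),
            all(parameters %in% names(data)))
  groups_present <- intersect(c("normal", "moderate", "severe"),
                              unique(data$group))
  strata <- if (by_compartment) c("group", "compartment") else "group"
  summ <- do.call(rbind, lapply(parameters, function(p) {
    agg <- do.call(rbind, by(data, data[strata], function(d) {
      x <- d[[p]]
      out <- data.frame(parameter = p, n = length(x), mean = mean(x),
                        sd = if (length(x) > 1) sd(x) else NA_real_,
                        median = median(x), iqr = stats::IQR(x))
      for (s in strata) out[[s]] <- d[[s]][1]
      out
    }, simplify = FALSE))
    agg
  }))
  rownames(summ) <- NULL

  contrasts <- NULL
  g1 <- data[data$group == "normal", ]
  g2 <- data[data$group == "moderate", ]
  small <- vapply(groups_present, function(g) sum(data$group == g) < min_n_test,
                  TRUE)
  if (nrow(g1) >= min_n_test && nrow(g2) >= min_n_test) {
    old_seed <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    alpha <- (1 - conf) / 2
    contrasts <- do.call(rbind, lapply(parameters, function(p) {
      bd <- boot_mean_diff(g1[[p]], g1$knee_id, g2[[p]], g2$knee_id, B)
      ci <- unname(quantile(bd, c(alpha, 1 - alpha)))
      data.frame(parameter = p, contrast = "moderate - normal",
                 estimate = mean(g2[[p]]) - mean(g1[[p]]),
                 ci_lower = ci[1], ci_upper = ci[2], B = B)
    }))
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }
  excluded <- groups_present[small]
  if (length(excluded) && !is.null(contrasts))
    attr(contrasts, "note") <-
      paste("descriptive only (n <", min_n_test, "):",
            paste(excluded, collapse = ", "))
  structure(list(summary = summ, contrasts = contrasts),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat("group summary:\n")
  print(x$summary, row.names = FALSE, digits = 4)
  if (!is.null(x$contrasts)) {
    cat("\ncontrasts (knee-clustered percentile bootstrap):\n")
    print(x$contrasts, row.names = FALSE, digits = 4)
    if (!is.null(attr(x$contrasts, "note")))
      cat(attr(x$contrasts, "note"), "\n")
  }
  invisible(x)
}
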