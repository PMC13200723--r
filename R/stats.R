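#' Two-group comparison with a recorded decision trail
#'
#' Implements a conventional physiology testing policy: Shapiro–Wilk normality
#' on each group at alpha 0.05; when both pass, a median-centred Levene test
#' decides between Student's (equal variances) and Welch's t-test; when either
#' group departs from normality, a Wilcoxon rank-sum test is used. Every
#' decision is recorded so the chosen branch is auditable. A specific branch
#' can be forced through `policy` (e.g. `"welch"` for endpoints with known
#' unequal variances).
#'
#' @param a,b numeric samples, each with at least 3 observations.
#' @param policy `"auto"` (the gated decision above) or one of `"welch"`,
#'   `"student"`, `"wilcoxon"` to force a branch.
#' @param alpha significance level for the normality and variance gates.
#' @return An object of class `comparison_result`: list with `test_name`,
#'   `statistic`, `df` (NA for the rank test), `p_value` and the character
#'   vector `decision_trail`.
#' @export
compare_groups <- function(a, b, policy = c("auto", "welch", "student",
                                            "wilcoxon"), alpha = 0.05) {
  policy <- match.arg(policy)
  a <- a[is.finite(a)]
  b <- b[is.finite(b)]
  if (length(a) < 3 || length(b) < 3) {
    stop("each group needs at least 3 observations", call. = FALSE)
  }
  trail <- character(0)
  choice <- policy
  if (policy == "auto") {
    normal <- vapply(list(a, b), function(x) {
      if (stats::sd(x) == 0) return(FALSE)  # degenerate: constant sample
      stats::shapiro.test(x)$p.value >= alpha
    }, logical(1))
    trail <- c(trail, sprintf("shapiro group1: %s",
                              if (normal[1]) "normal" else "non-normal"),
               sprintf("shapiro group2: %s",
                       if (normal[2]) "normal" else "non-normal"))
    if (all(normal)) {
      df_lev <- data.frame(y = c(a, b),
                           g = factor(rep(c("a", "b"), c(length(a), length(b)))))
      lev_p <- car::leveneTest(y ~ g, data = df_lev, center = median)[1, "Pr(>F)"]
      equal_var <- lev_p >= alpha
      trail <- c(trail, sprintf("levene: %s variances",
                                if (equal_var) "equal" else "unequal"))
      choice <- if (equal_var) "student" else "welch"
    } else {
      choice <- "wilcoxon"
    }
  } else {
    trail <- c(trail, sprintf("policy: %s", policy))
  }
  trail <- c(trail, sprintf("test: %s", choice))

  if (choice == "wilcoxon") {
    ht <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))
    res <- list(test_name = "Wilcoxon rank sum",
                statistic = unname(ht$statistic), df = NA_real_,
                p_value = ht$p.value)
  } else {
    ht <- stats::t.test(a, b, var.equal = (choice == "student"))
    res <- list(test_name = if (choice == "student") "Student t" else "Welch t",
                statistic = unname(ht$statistic), df = unname(ht$parameter),
                p_value = ht$p.value)
  }
  if (!is.finite(res$p_value)) res$p_value <- 1  # degenerate zero-variance case
  structure(c(res, list(decision_trail = trail)), class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s: statistic %.4g, df %.3g, p = %.4g\n",
              x$test_name, x$statistic, x$df, x$p_value))
  cat("  trail:", paste(x$decision_trail, collapse = " | "), "\n")
  invisible(x)
}

#' Two-way repeated-measures ANOVA with Tukey-adjusted week contrasts
#'
#' Fits the trial factor structure — a between-subject group factor crossed
#' with a within-subject week factor, subjects as the repeated unit — via a
#' univariate ANOVA with a subject error stratum, and follows up with
#' Tukey-adjusted pairwise contrasts between weeks (the repeated factor).
#'
#' @param table long-format data frame with columns `subject`, `genotype`,
#'   `week` and `value`; every subject must be observed in every week.
#' @return An object of class `rm_anova_result`: list with `effects` (tibble:
#'   `effect`, `df`, `df_error`, `F`, `p_value`) and `week_contrasts` (tibble
#'   of Tukey-adjusted pairwise week comparisons).
#' @export
rm_anova <- function(table) {
  dat <- as.data.frame(table)
  needed <- c("subject", "genotype", "week", "value")
  if (!all(needed %in% names(dat))) {
    stop("table needs columns: ", paste(needed, collapse = ", "), call. = FALSE)
  }
  dat$subject <- factor(dat$subject)
  dat$genotype <- factor(dat$genotype)
  dat$week <- factor(dat$week)

  grid <- table(dat$subject, dat$week)
  if (any(grid == 0)) {
    miss <- which(grid == 0, arr.ind = TRUE)
    cells <- apply(miss, 1, function(i) {
      paste0(rownames(grid)[i[1]], ":week", colnames(grid)[i[2]])
    })
    stop("missing cells: ", paste(cells, collapse = ", "), call. = FALSE)
  }

  all_equal <- max(dat$value) == min(dat$value)
  fit <- do.call(stats::aov,
                 list(formula = value ~ genotype * week + Error(subject),
                      data = dat))
  sm <- summary(fit)
  effects <- dplyr::bind_rows(lapply(sm, function(stratum) {
    tab <- stratum[[1]]
    rows <- trimws(rownames(tab))
    keep <- rows != "Residuals"
    if (!any(keep)) return(NULL)
    f_val <- tab$`F value`[keep]
    p_val <- tab$`Pr(>F)`[keep]
    # constant data leave only floating-point dust in every stratum; report
    # the null effect rather than a 0/0 artefact
    if (all_equal || any(!is.finite(f_val))) {
      degenerate <- all_equal | (!is.finite(f_val) & tab$`Sum Sq`[keep] < 1e-12)
      f_val[degenerate] <- 0
      p_val[degenerate] <- 1
    }
    tibble::tibble(effect = rows[keep],
                   df = tab$Df[keep],
                   df_error = tab$Df[rows == "Residuals"],
                   F = f_val,
                   p_value = p_val)
  }))

  emm <- suppressMessages(emmeans::emmeans(fit, ~week))
  contrasts <- suppressMessages(tibble::as_tibble(
    as.data.frame(emmeans::contrast(emm, method = "pairwise", adjust = "tukey"))))

  structure(list(effects = effects, week_contrasts = contrasts,
                 n_subjects = nlevels(table$subject)),
            class = "rm_anova_result")
}

#' @export
print.rm_anova_result <- function(x, ...) {
  cat(sprintf("<rm_anova_result> %d subjects\n", x$n_subjects))
  print(as.data.frame(x$effects), row.names = FALSE)
  invisible(x)
}
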