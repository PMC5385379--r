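check_panel <- function(panel) {
  need <- c("animal_id", "group", "analyte", "concentration", "units")
  if (!all(need %in% names(panel)))
    stop_ep("plasma panel needs columns: %s", paste(need, collapse = ", "))
  dup <- duplicated(panel[, c("animal_id", "analyte")])
  if (any(dup))
    stop_ep("duplicate (animal, analyte) records: %s",
            paste(unique(panel$animal_id[dup]), collapse = ", "))
  invisible(panel)
}

#' Derive the protective-axis ratios per animal
#'
#' Augments a long-format plasma panel with the two dimensionless ratios
#' used as endothelial readouts: `Ang-(1-7)/Ang II` (ACE2- vs ACE-axis
#' balance) and `L-Arg/ADMA` (a proxy of NO bioavailability). A zero
#' denominator makes the ratio undefined (`NA`) for that animal; the
#' affected animals are flagged in the `"undefined_ratios"` attribute.
#'
#' @param panel Plasma panel data frame (`animal_id`, `group`, `analyte`,
#'   `concentration`, `units`).
#' @return The panel with one extra record per animal and ratio
#'   (`units = "ratio"`).
#' @export
derive_ratios <- function(panel) {
  check_panel(panel)
  ratios <- list(
    c(name = "Ang-(1-7)/Ang II", num = "Ang-(1-7)", den = "Ang II"),
    c(name = "L-Arg/ADMA", num = "L-Arg", den = "ADMA")
  )
  flagged <- character(0)
  extra <- list()
  animals <- unique(panel[, c("animal_id", "group")])
  for (r in ratios) {
    num <- panel[panel$analyte == r[["num"]], c("animal_id", "concentration")]
    den <- panel[panel$analyte == r[["den"]], c("animal_id", "concentration")]
    for (i in seq_len(nrow(animals))) {
      id <- animals$animal_id[i]
      nv <- num$concentration[match(id, num$animal_id)]
      dv <- den$concentration[match(id, den$animal_id)]
      if (is.na(nv)) stop_ep("animal '%s' is missing analyte '%s'", id, r[["num"]])
      if (is.na(dv)) stop_ep("animal '%s' is missing analyte '%s'", id, r[["den"]])
      val <- if (dv == 0) NA_real_ else nv / dv
      if (dv == 0) flagged <- c(flagged, sprintf("%s: %s", id, r[["name"]]))
      extra[[length(extra) + 1L]] <- data.frame(
        animal_id = id, group = animals$group[i], analyte = r[["name"]],
        concentration = val, units = "ratio", stringsAsFactors = FALSE)
    }
  }
  out <- rbind(panel, do.call(rbind, extra))
  rownames(out) <- NULL
  attr(out, "undefined_ratios") <- flagged
  out
}

#' Percent change of a group location between two groups
#'
#' `100 * (loc_treated - loc_reference) / loc_reference`, where the
#' location is the group mean (analyte concentrations, reported as
#' mean +/- SEM) or median (non-parametric endpoints such as Npx50).
#'
#' @param panel Plasma panel, possibly augmented by [derive_ratios()].
#' @param analyte Analyte or ratio name.
#' @param reference_group,treated_group Group labels.
#' @param location `"mean"` (default) or `"median"`.
#' @return Percent change (scalar).
#' @export
group_percent_change <- function(panel, analyte, reference_group, treated_group,
                                 location = c("mean", "median")) {
  location <- match.arg(location)
  check_panel(panel)
  pick <- function(grp) {
    v <- panel$concentration[panel$analyte == analyte & panel$group == grp]
    v <- v[!is.na(v)]
    if (!length(v)) stop_ep("no records for analyte '%s' in group '%s'", analyte, grp)
    if (location == "mean") mean(v) else stats::median(v)
  }
  ref <- pick(reference_group); trt <- pick(treated_group)
  if (ref == 0) stop_ep("reference location is zero for '%s'", analyte)
  100 * (trt - ref) / ref
}

# Dunn's post-hoc test after Kruskal-Wallis: pairwise z statistics on mean
# ranks with the tie-corrected variance, Holm-adjusted.
dunn_posthoc <- function(values, groups) {
  groups <- factor(groups)
  n <- length(values); r <- rank(values)
  ties <- table(r)
  tiecorr <- sum(ties^3 - ties) / (12 * (n - 1))
  rbar <- tapply(r, groups, mean)
  ns <- tapply(r, groups, length)
  gl <- levels(groups)
  pairs <- utils::combn(gl, 2)
  z <- p <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1, k]; b <- pairs[2, k]
    se <- sqrt((n * (n + 1) / 12 - tiecorr) * (1 / ns[[a]] + 1 / ns[[b]]))
    z[k] <- (rbar[[a]] - rbar[[b]]) / se
    p[k] <- 2 * stats::pnorm(-abs(z[k]))
  }
  data.frame(comparison = paste(pairs[1, ], pairs[2, ], sep = " - "),
             statistic = z, p_value = p,
             p_adjusted = stats::p.adjust(p, "holm"),
             stringsAsFactors = FALSE)
}

#' Omnibus group comparison with post-hoc tests
#'
#' Non-parametric design: Kruskal-Wallis H (tie-corrected) with Dunn's
#' post-hoc pairwise z-tests, Holm-adjusted. Parametric design: one-way
#' ANOVA F with Tukey HSD. Per-group normality is recorded via the
#' Lilliefors (Kolmogorov-Smirnov) test where the group size allows
#' (n >= 5). Post-hoc tables are produced only for 3 or more groups; with
#' two groups the omnibus test reduces to the 2-sample case.
#'
#' @param values Numeric endpoint values.
#' @param groups Group labels (same length); every group needs n >= 2.
#' @param design `"nonparametric"` (default) or `"parametric"`.
#' @return Object of class `group_test_result` with `test`, `statistic`,
#'   `p_value`, `posthoc` (data frame or NULL) and `normality`.
#' @export
compare_groups <- function(values, groups,
                           design = c("nonparametric", "parametric")) {
  design <- match.arg(design)
  if (length(values) != length(groups)) stop_ep("'values' and 'groups' lengths differ")
  keep <- !is.na(values)
  values <- values[keep]; groups <- factor(as.character(groups[keep]))
  ns <- table(groups)
  if (nlevels(groups) < 2L) stop_ep("at least 2 groups are required")
  if (any(ns < 2L))
    stop_ep("every group needs n >= 2 (violated by: %s)",
            paste(names(ns)[ns < 2], collapse = ", "))
  normality <- lapply(split(values, groups), function(v) {
    if (length(v) >= 5L && stats::sd(v) > 0) {
      ks <- nortest::lillie.test(v)
      list(statistic = unname(ks$statistic), p_value = ks$p.value)
    } else list(statistic = NA_real_, p_value = NA_real_)
  })
  constant <- stats::sd(values) == 0
  if (design == "nonparametric") {
    if (constant) { stat <- 0; pval <- 1 }
    else {
      kt <- stats::kruskal.test(values, groups)
      stat <- unname(kt$statistic); pval <- kt$p.value
    }
    posthoc <- if (nlevels(groups) >= 3L && !constant)
      dunn_posthoc(values, groups) else NULL
    test <- "Kruskal-Wallis"
  } else {
    if (constant) { stat <- 0; pval <- 1; posthoc <- NULL }
    else {
      fit <- stats::aov(values ~ groups)
      s <- summary(fit)[[1]]
      stat <- s[["F value"]][1]; pval <- s[["Pr(>F)"]][1]
      posthoc <- if (nlevels(groups) >= 3L) {
        tk <- stats::TukeyHSD(fit)$groups
        data.frame(comparison = rownames(tk), difference = tk[, "diff"],
                   p_adjusted = tk[, "p adj"], row.names = NULL,
                   stringsAsFactors = FALSE)
      } else NULL
    }
    test <- "one-way ANOVA"
  }
  structure(list(test = test, statistic = stat, p_value = pval,
                 posthoc = posthoc, normality = normality,
                 n = as.vector(ns), groups = levels(groups)),
            class = "group_test_result")
}

#' @export
print.group_test_result <- function(x, ...) {
  cat(sprintf("<group_test_result> %s: statistic = %.4g, p = %.4g\n",
              x$test, x$statistic, x$p_value))
  cat(sprintf("  groups: %s (n = %s)\n", paste(x$groups, collapse = ", "),
              paste(x$n, collapse = ", ")))
  if (!is.null(x$posthoc)) { cat("  post-hoc:\n"); print(x$posthoc) }
  invisible(x)
}

#' Correlation between a functional and a biochemical readout
#'
#' Pearson or Spearman correlation with a two-sided p-value. Spearman is
#' computed as Pearson on average ranks (the tie-robust definition), with
#' the p-value from the t approximation.
#'
#' @param x,y Paired per-animal values, n >= 3.
#' @param method `"spearman"` (default, as used for the published
#'   function-biochemistry pairs) or `"pearson"`.
#' @param labels Optional length-2 variable names for the report.
#' @return Object of class `correlation_result` with `method`, `r`,
#'   `p_value`, `n`, `pair`.
#' @export
correlate <- function(x, y, method = c("spearman", "pearson"),
                      labels = c("x", "y")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop_ep("'x' and 'y' lengths differ")
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop_ep("need n >= 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_ep("constant vector: correlation undefined")
  if (method == "spearman") { x <- rank(x); y <- rank(y) }
  ct <- stats::cor.test(x, y, method = "pearson")
  structure(list(method = method, r = unname(ct$estimate),
                 p_value = ct$p.value, n = length(x),
                 pair = labels),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> %s vs %s: %s r = %.4f, p = %.4g (n = %d)\n",
              x$pair[1], x$pair[2], x$method, x$r, x$p_value, x$n))
  invisible(x)
}

#' Joint functional-biochemical cohort profile
#'
#' Joins per-animal imaging endpoints with the plasma panel and reproduces
#' the published pairing structure: Spearman correlations of
#' {BCA volume change, Npx50} x {L-Arg/ADMA, Ang-(1-7)/Ang II} plus
#' volume change x Npx50, group summary statistics, and treated-vs-
#' reference percent-change tables.
#'
#' @param imaging Data frame with `animal_id`, `group`,
#'   `bca_volume_change_pct`, `npx50` (one row per animal).
#' @param panel Plasma panel for the same animals; ratios are derived
#'   internally if absent.
#' @param reference_group Group used as the percent-change reference
#'   (default: first group alphabetically containing "Untreated", else
#'   the first group).
#' @return Object of class `cohort_profile` with `correlations` (data
#'   frame of the five pairs), `group_summary`, `percent_change`,
#'   `group_tests` and the joined per-animal table (`animals`).
#' @export
profile_cohort <- function(imaging, panel, reference_group = NULL) {
  need <- c("animal_id", "group", "bca_volume_change_pct", "npx50")
  if (!all(need %in% names(imaging)))
    stop_ep("imaging table needs columns: %s", paste(need, collapse = ", "))
  check_panel(panel)
  if (!"L-Arg/ADMA" %in% panel$analyte) panel <- derive_ratios(panel)
  orphans_i <- setdiff(imaging$animal_id, panel$animal_id)
  orphans_p <- setdiff(panel$animal_id, imaging$animal_id)
  if (length(orphans_i) || length(orphans_p))
    stop_ep("animal_id mismatch between imaging and panel; orphans: %s",
            paste(c(orphans_i, orphans_p), collapse = ", "))
  imaging <- imaging[order(imaging$animal_id), ]
  wide <- stats::reshape(
    panel[, c("animal_id", "analyte", "concentration")],
    idvar = "animal_id", timevar = "analyte", direction = "wide")
  names(wide) <- sub("^concentration\\.", "", names(wide))
  animals <- merge(imaging, wide, by = "animal_id", sort = TRUE)

  pairs <- list(
    c("bca_volume_change_pct", "npx50", "BCA volume change", "Npx50"),
    c("bca_volume_change_pct", "L-Arg/ADMA", "BCA volume change", "L-Arg/ADMA ratio"),
    c("bca_volume_change_pct", "Ang-(1-7)/Ang II", "BCA volume change", "Ang-(1-7)/Ang II ratio"),
    c("npx50", "L-Arg/ADMA", "Npx50", "L-Arg/ADMA ratio"),
    c("npx50", "Ang-(1-7)/Ang II", "Npx50", "Ang-(1-7)/Ang II ratio")
  )
  cors <- do.call(rbind, lapply(pairs, function(p) {
    cr <- correlate(animals[[p[1]]], animals[[p[2]]], "spearman", p[3:4])
    data.frame(pair = paste(p[3], "and", p[4]), r_spearman = cr$r,
               p_value = cr$p_value, n = cr$n, stringsAsFactors = FALSE)
  }))

  full <- rbind(
    panel[, c("animal_id", "group", "analyte", "concentration", "units")],
    data.frame(animal_id = imaging$animal_id, group = imaging$group,
               analyte = "BCA volume change", concentration = imaging$bca_volume_change_pct,
               units = "%", stringsAsFactors = FALSE),
    data.frame(animal_id = imaging$animal_id, group = imaging$group,
               analyte = "Npx50", concentration = imaging$npx50,
               units = "pixels", stringsAsFactors = FALSE))
  agg <- function(f) stats::aggregate(concentration ~ analyte + group, full, f)
  gm <- agg(function(v) mean(v, na.rm = TRUE))
  gsem <- agg(function(v) stats::sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v))))
  gmed <- agg(function(v) stats::median(v, na.rm = TRUE))
  group_summary <- data.frame(gm[, c("group", "analyte")], mean = gm$concentration,
                              sem = gsem$concentration, median = gmed$concentration)
  group_summary <- group_summary[order(group_summary$analyte, group_summary$group), ]
  rownames(group_summary) <- NULL

  groups <- unique(full$group)
  if (is.null(reference_group)) {
    hit <- grep("Untreated", groups, value = TRUE)
    reference_group <- if (length(hit)) hit[1] else groups[1]
  }
  treated <- setdiff(groups, reference_group)
  pc <- do.call(rbind, lapply(unique(full$analyte), function(an) {
    loc <- if (an %in% c("Npx50", "BCA volume change")) "median" else "mean"
    do.call(rbind, lapply(treated, function(tg) {
      v <- tryCatch(group_percent_change(full, an, reference_group, tg, loc),
                    error = function(e) NA_real_)
      data.frame(analyte = an, treated_group = tg, location = loc,
                 percent_change = v, stringsAsFactors = FALSE)
    }))
  }))

  tests <- list(
    bca_volume_change = compare_groups(imaging$bca_volume_change_pct,
                                       imaging$group, "nonparametric"),
    npx50 = compare_groups(imaging$npx50, imaging$group, "nonparametric"))

  structure(list(correlations = cors, group_summary = group_summary,
                 percent_change = pc, group_tests = tests,
                 reference_group = reference_group, animals = animals),
            class = "cohort_profile")
}

#' @export
print.cohort_profile <- function(x, ...) {
  cat("<cohort_profile>\n")
  cat(sprintf("  %d animals, reference group: %s\n",
              nrow(x$animals), x$reference_group))
  cat("  function-biochemistry correlations (Spearman):\n")
  print(x$correlations, row.names = FALSE)
  invisible(x)
}
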