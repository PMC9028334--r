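# Block-based statistical pipeline: functional-state classification,
# contingency/chi-square association, test-selection logic and slice-wise
# Spearman correlation of dipole angles.

#' Build a per-channel, per-block observable table
#'
#' Runs [count_crossings()] and [water_count_per_block()] over the channels
#' of one or more conditions and assembles the long-format block table that
#' feeds the statistics pipeline: one row per (condition, channel, block)
#' with the per-block water count through the section.
#'
#' @param conditions Named list; each element is a list of per-channel
#'   [trajectory()] objects, or of precomputed `"PermeationEvents"`.
#' @param selection Selection applied to each trajectory (ignored for
#'   precomputed events).
#' @param geometry A [pore_geometry()] (ignored for precomputed events).
#' @param block_length Block length in ns (default 10).
#' @return `"BlockTable"` data frame `(condition, channel, block,
#'   water_count)`.
#' @export
build_block_table <- function(conditions, selection = NULL, geometry = NULL,
                              block_length = 10) {
  if (is.null(names(conditions)) || any(!nzchar(names(conditions))))
    stop("'conditions' must be a fully named list")
  rows <- list()
  for (cond in names(conditions)) {
    channels <- conditions[[cond]]
    for (ch in seq_along(channels)) {
      obj <- channels[[ch]]
      ev <- if (inherits(obj, "PermeationEvents")) obj
      else count_crossings(obj, selection, geometry)
      wb <- water_count_per_block(ev, block_length)
      rows[[length(rows) + 1L]] <-
        data.frame(condition = cond, channel = ch, block = wb$block,
                   water_count = wb$count, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "block_length") <- block_length
  class(out) <- c("BlockTable", "data.frame")
  out
}

#' Classify blocks into functional states
#'
#' A 10 ns block is called functional when the number of waters crossing
#' the whole transmembrane section reaches the threshold (inclusive: a
#' count equal to the threshold is functional). The default threshold of 5
#' discriminates open from blocked channels.
#'
#' @param table A `"BlockTable"` (or any data frame with a `water_count`
#'   column).
#' @param threshold Functional-state threshold, waters per block (default 5).
#' @return The table with a logical `functional` column appended
#'   (class `"StateCalls"`).
#' @export
classify_blocks <- function(table, threshold = 5) {
  if (is.null(table$water_count)) stop("table lacks a 'water_count' column")
  table$functional <- table$water_count >= threshold
  attr(table, "threshold") <- threshold
  class(table) <- unique(c("StateCalls", class(table)))
  table
}

#' Chi-square association between two binary factors
#'
#' Pearson chi-square test on the 2x2 contingency table of two binary
#' variables (e.g. classified functional state versus ligand-bound state),
#' without continuity correction by default. Table orientation is fixed:
#' rows = first factor (`FALSE`, `TRUE`), columns = second factor.
#'
#' @param x Either a 2x2 matrix/table of counts, or a logical/two-level
#'   vector.
#' @param y Second logical/two-level vector when `x` is a vector.
#' @param correct Apply the Yates continuity correction (default `FALSE`).
#' @return List of class `"Chi2Result"`: `table`, `statistic`, `df`,
#'   `p_value`, `expected`. A table with a zero margin is an error
#'   (association undefined).
#' @export
contingency_chi2 <- function(x, y = NULL, correct = FALSE) {
  tab <- if (is.matrix(x) || is.table(x)) as.matrix(x) else {
    if (is.null(y)) stop("supply either a 2x2 table or two vectors")
    if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
    table(factor(x, levels = sort(unique(c(FALSE, TRUE, x)))[1:2]),
          factor(y, levels = sort(unique(c(FALSE, TRUE, y)))[1:2]))
  }
  if (!all(dim(tab) == c(2L, 2L))) stop("contingency table must be 2x2")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero margin in contingency table: association undefined")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  structure(list(table = tab, statistic = unname(ct$statistic),
                 df = unname(ct$parameter), p_value = ct$p.value,
                 expected = ct$expected, correct = correct),
            class = "Chi2Result")
}

#' @export
print.Chi2Result <- function(x, ...) {
  cat(sprintf("Pearson chi-square%s: X2 = %.4g, df = %d, p = %.4g\n",
              if (x$correct) " (Yates-corrected)" else "", x$statistic, x$df,
              x$p_value))
  print(x$table)
  invisible(x)
}

#' Compare groups with automatic parametric/non-parametric selection
#'
#' The test-selection rule of the pipeline: Shapiro-Wilk normality in every
#' group and Levene homoscedasticity, both at `alpha`. If all pass, the
#' parametric branch is used: Student's t-test for two groups, one-way
#' ANOVA with Tukey's post hoc for more. Otherwise the rank branch:
#' Mann-Whitney for two groups, pairwise Wilcoxon rank-sum tests with
#' Bonferroni correction (Kruskal-Wallis omnibus) for more. A group with
#' constant data forces the rank branch (Shapiro is undefined there).
#'
#' @param values Numeric observations.
#' @param groups Group labels (coerced to factor), `>= 2` levels with
#'   `n >= 3` each.
#' @param paired Paired comparisons (two groups only; default `FALSE`).
#' @param alpha Significance level of the assumption checks (default 0.05).
#' @return `"ComparisonResult"`: list with `test_name`, `statistic`,
#'   `p_value` (omnibus), `group_labels`, `normality_p` (named per group),
#'   `homoscedasticity_p`, `parametric`, `pairwise` (data frame of post hoc
#'   p-values for `> 2` groups, else `NULL`), `correction`, `notes`.
#' @export
compare_groups <- function(values, groups, paired = FALSE, alpha = 0.05) {
  groups <- droplevels(as.factor(groups))
  if (length(values) != length(groups)) stop("'values' and 'groups' lengths differ")
  k <- nlevels(groups)
  if (k < 2) stop("need at least two groups")
  ns <- table(groups)
  if (any(ns < 3)) stop("every group needs n >= 3")
  if (paired && k != 2) stop("paired comparisons require exactly two groups")
  notes <- character(0)
  sw <- vapply(levels(groups), function(g) {
    v <- values[groups == g]
    if (stats::sd(v) == 0) return(0)     # constant data: normality untestable
    stats::shapiro.test(v)$p.value
  }, numeric(1))
  constant <- vapply(levels(groups), function(g) stats::sd(values[groups == g]) == 0,
                     logical(1))
  if (any(constant)) notes <- c(notes, "constant data in a group: rank branch forced")
  lev <- tryCatch(car::leveneTest(values ~ groups)[1, "Pr(>F)"],
                  error = function(e) 0)
  parametric <- all(sw > alpha) && lev > alpha && !any(constant)
  pairwise <- NULL
  if (k == 2L) {
    if (parametric) {
      tt <- stats::t.test(values ~ groups, var.equal = TRUE, paired = paired)
      test_name <- if (paired) "paired Student's t-test" else "Student's t-test"
      statistic <- unname(tt$statistic); p <- tt$p.value
      correction <- "none"
    } else {
      wt <- suppressWarnings(stats::wilcox.test(values ~ groups, paired = paired))
      test_name <- if (paired) "Wilcoxon signed-rank" else "Mann-Whitney"
      statistic <- unname(wt$statistic); p <- wt$p.value
      correction <- "none"
    }
  } else {
    if (parametric) {
      fit <- stats::aov(values ~ groups)
      an <- summary(fit)[[1]]
      statistic <- an[1, "F value"]; p <- an[1, "Pr(>F)"]
      tk <- stats::TukeyHSD(fit)$groups
      pairwise <- data.frame(comparison = rownames(tk), p_adj = tk[, "p adj"],
                             row.names = NULL)
      test_name <- "one-way ANOVA + Tukey HSD"
      correction <- "Tukey"
    } else {
      kw <- stats::kruskal.test(values ~ groups)
      statistic <- unname(kw$statistic); p <- kw$p.value
      pw <- suppressWarnings(stats::pairwise.wilcox.test(values, groups,
                                                         p.adjust.method = "bonferroni"))
      m <- pw$p.value
      comp <- expand.grid(a = rownames(m), b = colnames(m), stringsAsFactors = FALSE)
      keep <- !is.na(as.vector(m))
      pairwise <- data.frame(comparison = paste(comp$a, comp$b, sep = "-")[keep],
                             p_adj = as.vector(m)[keep])
      test_name <- "pairwise Wilcoxon rank-sum + Bonferroni (Kruskal-Wallis omnibus)"
      correction <- "Bonferroni"
    }
  }
  structure(list(test_name = test_name, statistic = statistic, p_value = p,
                 group_labels = levels(groups), normality_p = sw,
                 homoscedasticity_p = lev, parametric = parametric,
                 pairwise = pairwise, correction = correction, notes = notes),
            class = "ComparisonResult")
}

#' @export
print.ComparisonResult <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (%s branch)\n", x$test_name,
              x$statistic, x$p_value,
              if (x$parametric) "parametric" else "non-parametric"))
  if (!is.null(x$pairwise)) {
    cat("post hoc:\n"); print(x$pairwise)
  }
  invisible(x)
}

#' Slab-wise Spearman correlation of dipole angles
#'
#' Divides the box along z into slabs and, for the frames in which the
#' ligand's centre of geometry falls inside each slab, computes the
#' Spearman rank correlation between the protein and ligand dipole-angle
#' series. Slabs with fewer than `min_frames` frames are reported as
#' insufficient data rather than tested.
#'
#' @param protein_angles,ligand_angles Numeric angle series (degrees),
#'   aligned frame by frame.
#' @param ligand_z Ligand centre-of-geometry z per frame, Angstrom.
#' @param slab_width Slab thickness, Angstrom (default 10).
#' @param z_range `c(lo, hi)` slab grid extent; default the range of
#'   `ligand_z`.
#' @param min_frames Minimum frames per testable slab (default 5).
#' @return Data frame `(z_lo, z_hi, n, rho, p_value, status)` with `status`
#'   either `"ok"` or `"insufficient data"`.
#' @export
slice_dipole_correlation <- function(protein_angles, ligand_angles, ligand_z,
                                     slab_width = 10, z_range = NULL,
                                     min_frames = 5L) {
  n <- length(protein_angles)
  if (length(ligand_angles) != n || length(ligand_z) != n)
    stop("angle series and ligand z must be aligned in time")
  if (is.null(z_range)) z_range <- range(ligand_z)
  edges <- seq(floor(z_range[1] / slab_width) * slab_width,
               ceiling(z_range[2] / slab_width) * slab_width, by = slab_width)
  if (length(edges) < 2) edges <- c(edges, edges + slab_width)
  nb <- length(edges) - 1L
  slab <- findInterval(ligand_z, edges, rightmost.closed = TRUE)
  out <- data.frame(z_lo = edges[-(nb + 1)], z_hi = edges[-1],
                    n = NA_integer_, rho = NA_real_, p_value = NA_real_,
                    status = "insufficient data", stringsAsFactors = FALSE)
  for (b in seq_len(nb)) {
    sel <- which(slab == b)
    out$n[b] <- length(sel)
    if (length(sel) >= min_frames) {
      ct <- suppressWarnings(stats::cor.test(protein_angles[sel], ligand_angles[sel],
                                             method = "spearman"))
      out$rho[b] <- unname(ct$estimate)
      out$p_value[b] <- ct$p.value
      out$status[b] <- "ok"
    }
  }
  out
}

#' Assemble a structured analysis report
#'
#' Bundles any subset of completed analyses into a deterministic,
#' serializable report with a provenance header (package version, seed,
#' parameters, input labels). With `file` set, the report is written as
#' JSON (and per-table CSV files next to it with `csv = TRUE`). Rerunning
#' with the same inputs and seed yields a byte-identical JSON body.
#'
#' @param results Named list of analysis results (data frames or lists).
#' @param file Optional JSON output path.
#' @param seed Seed to record in the provenance header.
#' @param parameters Named list of parameters to record.
#' @param csv Also write each data-frame result as CSV (default `FALSE`).
#' @return The report list, invisibly when writing.
#' @export
build_report <- function(results = list(), file = NULL, seed = NULL,
                         parameters = list(), csv = FALSE) {
  if (length(results) > 0 && (is.null(names(results)) || any(!nzchar(names(results)))))
    stop("'results' must be a named list")
  report <- list(
    provenance = list(
      package = "poreflux",
      version = as.character(utils::packageVersion("poreflux")),
      seed = seed,
      parameters = parameters,
      results_included = names(results)),
    results = results)
  if (!is.null(file)) {
    jsonlite::write_json(report, file, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns", null = "null", force = TRUE)
    if (csv) {
      base <- sub("\\.json$", "", file)
      for (nm in names(results)) {
        if (is.data.frame(results[[nm]]))
          utils::write.csv(results[[nm]], sprintf("%s_%s.csv", base, nm),
                           row.names = FALSE)
      }
    }
    return(invisible(report))
  }
  report
}
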