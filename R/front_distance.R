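# The core statistic: per-spot distances from the invasive and nuclear
# edges of a leader cell, normalized per spot to d = Id / (Id + Nd) in
# [0, 1] (0 = invasive edge, 1 = nuclear edge), averaged per cell and
# species, compared against an internally co-detected control RNA and
# across conditions.

#' Per-spot normalized front distances
#'
#' For each spot, Id and Nd are the minimum Euclidean distances to the
#' invasive and nuclear edge polylines; the total protrusion length at that
#' spot is L = Id + Nd and the normalized distance d = Id / L. Spots whose
#' L falls below `min_length_um` carry no positional information (the two
#' edges effectively touch there) and are dropped with a warning.
#'
#' @param spots a [detect_spots] `spot_set`, or a data.frame with columns
#'   species, x_um, y_um.
#' @param edges an [edge_annotation].
#' @param min_length_um floor on L below which records are dropped.
#' @return data.frame with spot_id, species, Id_um, Nd_um, L_um, d.
#' @export
spot_edge_distances <- function(spots, edges, min_length_um = 0.1) {
  stopifnot(inherits(edges, "edge_annotation"))
  df <- if (inherits(spots, "spot_set")) spots$spots else as.data.frame(spots)
  if (nrow(df) == 0L) stop("no spots supplied")
  pts <- as.matrix(df[, c("x_um", "y_um")])
  Id <- point_polyline_distance(pts, edges$invasive_edge)
  Nd <- point_polyline_distance(pts, edges$nuclear_edge)
  L <- Id + Nd
  out <- data.frame(spot_id = seq_len(nrow(df)),
                    species = if ("species" %in% names(df)) df$species else "unknown",
                    Id_um = Id, Nd_um = Nd, L_um = L, d = Id / L,
                    stringsAsFactors = FALSE)
  short <- out$L_um < min_length_um
  if (any(short)) {
    warning(sum(short), " spot(s) dropped: protrusion length below ",
            format(min_length_um), " um")
    out <- out[!short, , drop = FALSE]
  }
  out
}

#' Per-cell average normalized distance
#'
#' The default ("per_spot") averages the per-spot normalized distances d,
#' treating the protrusion length as a per-spot quantity. The alternative
#' "average_then_normalize" first averages the raw edge distances and then
#' normalizes, mean(Id) / (mean(Id) + mean(Nd)); it is provided for
#' comparison but is not the default reading.
#'
#' @param records output of [spot_edge_distances].
#' @param cell_id identifier carried into the summary.
#' @param species species to summarize; default all present.
#' @param normalization "per_spot" (default) or "average_then_normalize".
#' @return data.frame with cell_id, species, n_spots, mean_d (one row per
#'   species).
#' @export
summarize_cell <- function(records, cell_id, species = NULL,
                           normalization = c("per_spot", "average_then_normalize")) {
  normalization <- match.arg(normalization)
  if (is.null(species)) species <- unique(records$species)
  rows <- lapply(species, function(sp) {
    r <- records[records$species == sp, , drop = FALSE]
    if (nrow(r) == 0L) {
      warning("cell ", cell_id, ": no '", sp, "' spots; species excluded")
      return(NULL)
    }
    m <- if (normalization == "per_spot") mean(r$d)
         else mean(r$Id_um) / (mean(r$Id_um) + mean(r$Nd_um))
    data.frame(cell_id = cell_id, species = sp, n_spots = nrow(r),
               mean_d = m, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Probability density of per-cell mean distances
#'
#' Gaussian kernel density of the per-cell mean normalized distances on
#' [0, 1] with boundary reflection at both ends, so that no probability
#' mass leaks outside the support; the result integrates to 1 by the
#' trapezoidal rule. Bandwidth defaults to Silverman's rule of thumb.
#'
#' @param summaries data.frame from [summarize_cell] (one species).
#' @param bandwidth kernel bandwidth; NULL for Silverman's rule.
#' @param n_grid number of grid points on [0, 1].
#' @return list with `support`, `density`, `bandwidth`, `n_cells`.
#' @export
density_of_means <- function(summaries, bandwidth = NULL, n_grid = 512L) {
  x <- summaries$mean_d
  if (length(x) < 3L) stop("need at least 3 cells for a density estimate")
  if (any(x < 0 | x > 1)) stop("mean_d outside [0, 1]")
  if (is.null(bandwidth)) {
    if (stats::sd(x) == 0) {
      warning("degenerate (identical) means; using a narrow fallback kernel")
      bandwidth <- 1e-3
    } else {
      bandwidth <- stats::bw.nrd0(x)
    }
  }
  grid <- seq(0, 1, length.out = n_grid)
  # reflect the sample at both boundaries and evaluate the plain Gaussian KDE
  aug <- c(x, -x, 2 - x)
  dens <- vapply(grid, function(g) {
    mean(stats::dnorm(g, mean = aug, sd = bandwidth)) * 3
  }, numeric(1L))
  integral <- sum(diff(grid) * (dens[-1L] + dens[-n_grid]) / 2)
  dens <- dens / integral
  list(support = grid, density = dens, bandwidth = bandwidth,
       n_cells = length(x))
}

#' Paired target-vs-control shift test
#'
#' Two-sided Wilcoxon signed-rank test on per-cell differences between the
#' mean normalized distance of a target RNA and of the internally
#' co-detected control RNA, paired strictly by cell_id. The exact null
#' distribution is used for n <= 25 (absent ties), the normal approximation
#' with continuity correction above; zero differences are dropped per the
#' Wilcoxon convention and ties are mid-ranked.
#'
#' @param target,control data.frames from [summarize_cell] (columns cell_id,
#'   mean_d), one species each.
#' @return list with n_pairs, statistic, p_value, median_paired_difference.
#' @export
paired_shift_test <- function(target, control) {
  unmatched <- c(setdiff(target$cell_id, control$cell_id),
                 setdiff(control$cell_id, target$cell_id))
  if (length(unmatched) > 0L)
    stop("unmatched cell_id(s): ", paste(unique(unmatched), collapse = ", "))
  if (anyDuplicated(target$cell_id) || anyDuplicated(control$cell_id))
    stop("duplicated cell_id within a species")
  control <- control[match(target$cell_id, control$cell_id), , drop = FALSE]
  diffs <- target$mean_d - control$mean_d
  n <- length(diffs)
  if (n < 6L) stop("need at least 6 matched pairs")
  nz <- diffs[diffs != 0]
  if (length(nz) == 0L) {
    warning("all paired differences are zero; p = 1")
    return(list(n_pairs = n, statistic = NA_real_, p_value = 1,
                median_paired_difference = 0))
  }
  wt <- suppressWarnings(
    stats::wilcox.test(target$mean_d, control$mean_d, paired = TRUE,
                       exact = length(nz) <= 25L, correct = TRUE))
  list(n_pairs = n, statistic = unname(wt$statistic),
       p_value = wt$p.value, median_paired_difference = stats::median(diffs))
}

#' Many-to-one condition comparisons of per-cell means
#'
#' Compares each condition against a named reference, either by one-way
#' ANOVA with Dunnett's many-to-one adjustment or by the Kruskal-Wallis
#' test followed by Dunn's tie-corrected z tests, Bonferroni-adjusted over
#' the many-to-one family.
#'
#' @param per_cell_values named list mapping condition to a numeric vector
#'   of per-cell mean normalized distances.
#' @param method "anova_dunnett" or "kruskal_dunn".
#' @param reference name of the reference condition.
#' @return data.frame with condition, estimate (difference in means, or
#'   Dunn z), p_adjusted; attribute "omnibus_p" carries the ANOVA or
#'   Kruskal-Wallis p-value.
#' @export
compare_groups <- function(per_cell_values,
                           method = c("anova_dunnett", "kruskal_dunn"),
                           reference = names(per_cell_values)[1L]) {
  method <- match.arg(method)
  if (length(per_cell_values) < 2L) stop("need at least 2 conditions")
  if (!reference %in% names(per_cell_values))
    stop("reference condition '", reference, "' not present")
  sizes <- vapply(per_cell_values, length, integer(1L))
  if (any(sizes < 2L))
    stop("condition(s) with fewer than 2 values: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  cond_levels <- c(reference, setdiff(names(per_cell_values), reference))
  df <- data.frame(
    value = unlist(per_cell_values, use.names = FALSE),
    condition = factor(rep(names(per_cell_values), sizes), levels = cond_levels))

  if (method == "anova_dunnett") {
    fit <- stats::aov(value ~ condition, data = df)
    omnibus <- summary(fit)[[1L]][["Pr(>F)"]][1L]
    glt <- multcomp::glht(fit, linfct = multcomp::mcp(condition = "Dunnett"))
    sm <- summary(glt)
    out <- data.frame(condition = cond_levels[-1L],
                      estimate = unname(sm$test$coefficients),
                      p_adjusted = unname(sm$test$pvalues),
                      stringsAsFactors = FALSE)
  } else {
    kw <- stats::kruskal.test(value ~ condition, data = df)
    omnibus <- kw$p.value
    r <- rank(df$value)
    N <- nrow(df)
    tie_tab <- table(df$value)
    tie_corr <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
    v0 <- N * (N + 1) / 12
    rbar <- tapply(r, df$condition, mean)
    nn <- tapply(r, df$condition, length)
    others <- cond_levels[-1L]
    var_term <- (v0 - tie_corr) * (1 / nn[others] + 1 / nn[reference])
    z <- ifelse(var_term > 0,
                (rbar[others] - rbar[reference]) / sqrt(pmax(var_term, 0)),
                0)  # every observation tied: no evidence of a shift
    p <- pmin(1, 2 * stats::pnorm(-abs(z)) * length(others))
    out <- data.frame(condition = others, estimate = unname(z),
                      p_adjusted = unname(p), stringsAsFactors = FALSE)
  }
  attr(out, "omnibus_p") <- omnibus
  attr(out, "method") <- method
  attr(out, "reference") <- reference
  out
}
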