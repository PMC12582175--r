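#' Layer-annotation token lists used for grouping cortical clusters
#'
#' The grouping maps cluster labels to putative layers by exact substring
#' match against these annotation tokens. The retrosplenial-specific cluster
#' `"133_L2 IT RSPv-POST-PRE"` — the transcriptomic correlate of the
#' low-rheobase (LR) neurons of granular retrosplenial L2/3 — is assigned to
#' `"L2/3 LR"` with priority over the generic L2 rule.
#' @keywords internal
layer_token_lists <- function() {
  list(
    `L2/3 LR` = c("133_L2 IT RSPv-POST-PRE"),
    `L2/3` = c("L2 IT", "L2/3 IT"),
    L5 = c("L4 RSP-ACA", "L4 IT CTX", "L4/5 IT CTX", "L5 IT CTX",
           "L5 PT CTX", "L5 PPP", "L5/6 IT CTX", "L5/6 IT TPE-ENT"),
    L6 = c("L6 IT CTX", "L6 IT ENTl", "L5/6 NP CTX", "L6 CT CTX",
           "L6b CTX", "Car3"))
}

#' Assign putative layer groups from cluster labels
#'
#' Adds a `layer_group` column (`"L2/3"`, `"L5"`, `"L6"`, `"L2/3 LR"`, or
#' `"unassigned"`) by exact-substring matching of each cell's
#' `cluster_label` against the annotation token lists of
#' [layer_token_lists()]. The LR cluster match takes priority; within the
#' remaining lists the first matching group in the order L2/3, L5, L6 wins;
#' unmatched labels become `"unassigned"`. The operation is deterministic
#' and idempotent.
#'
#' @param table data frame with a `cluster_label` column (e.g. from
#'   [generate_cell_table()]).
#' @return `table` with a `layer_group` column appended (replaced if
#'   already present).
#' @export
assign_layer_groups <- function(table) {
  table <- as.data.frame(table)
  stopifnot("cluster_label" %in% names(table))
  lists <- layer_token_lists()
  labels <- as.character(table$cluster_label)
  out <- rep("unassigned", length(labels))
  for (grp in c("L2/3", "L5", "L6")) {
    hit <- Reduce(`|`, lapply(lists[[grp]],
                              function(tok) grepl(tok, labels, fixed = TRUE)))
    out[hit & out == "unassigned"] <- grp
  }
  lr <- Reduce(`|`, lapply(lists[["L2/3 LR"]],
                           function(tok) grepl(tok, labels, fixed = TRUE)))
  out[lr] <- "L2/3 LR"
  table$layer_group <- out
  table
}

#' Group contrasts of target-gene expression
#'
#' Contrasts per-cell counts between annotated groups: a two-tailed
#' unpaired t test when exactly two groups are compared, or a one-way ANOVA
#' with Dunnett many-to-one comparisons against a reference group otherwise
#' (both delegated to the group-statistics module). Also reports per-group
#' mean, SD, n and the fraction of cells with non-zero counts ("detectable"
#' fraction).
#'
#' @param table cell table with a `target_gene_count` column.
#' @param group_by grouping column name (`"region_label"` or
#'   `"layer_group"`).
#' @param reference reference group label (for Dunnett) or, with exactly
#'   two groups present, ignored.
#' @param groups optional character vector restricting/ordering the groups.
#' @return list: `group_summaries` (data frame: group, n, mean, sd,
#'   detectable_fraction), and `test` (a `stat_result` for a pair, an
#'   [anova_dunnett()] result otherwise).
#' @export
screen_contrast <- function(table, group_by = "layer_group",
                            reference = NULL, groups = NULL) {
  table <- as.data.frame(table)
  stopifnot(group_by %in% names(table),
            "target_gene_count" %in% names(table))
  gvals <- as.character(table[[group_by]])
  if (is.null(groups)) groups <- unique(gvals)
  samples <- lapply(groups, function(g) table$target_gene_count[gvals == g])
  names(samples) <- groups
  if (any(lengths(samples) == 0L))
    stop("empty group in contrast", call. = FALSE)
  summ <- data.frame(
    group = groups,
    n = lengths(samples),
    mean = vapply(samples, mean, numeric(1)),
    sd = vapply(samples, stats::sd, numeric(1)),
    detectable_fraction = vapply(samples, function(v) mean(v > 0),
                                 numeric(1)),
    row.names = NULL)
  test <- if (length(samples) == 2L) {
    compare_groups(samples[[1L]], samples[[2L]], design = "unpaired",
                   measure_class = "other")
  } else {
    ref_i <- if (is.null(reference)) 1L else match(reference, groups)
    if (is.na(ref_i)) stop("reference group not present", call. = FALSE)
    anova_dunnett(samples, reference_index = ref_i)
  }
  list(group_summaries = summ, test = test)
}
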