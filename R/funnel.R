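#' Presence rule for detection filtering
#'
#' A protein passes a presence rule within a sample scope when it is detected
#' (intensity > 0) in enough of the scoped samples: in at least `k` of them
#' (`mode = "at_least_k"`, e.g. two of three biological replicates) or in all
#' of them (`mode = "all"`).
#'
#' @param lineage,source,unit_id optional scope selectors; `NULL` means "any".
#' @param mode `"at_least_k"` or `"all"`.
#' @param k minimum detection count when `mode = "at_least_k"`.
#' @return An object of class `presence_rule`.
#' @export
presence_rule <- function(lineage = NULL, source = NULL, unit_id = NULL,
                          mode = c("at_least_k", "all"), k = 1L) {
  mode <- match.arg(mode)
  if (mode == "at_least_k" && (!is.numeric(k) || k < 1)) {
    stop("k must be a positive integer", call. = FALSE)
  }
  structure(list(lineage = lineage, source = source, unit_id = unit_id,
                 mode = mode, k = as.integer(k)),
            class = "presence_rule")
}

select_samples <- function(table, lineage = NULL, source = NULL,
                           unit_id = NULL) {
  keep <- rep(TRUE, nrow(table$samples))
  if (!is.null(lineage)) keep <- keep & table$samples$lineage %in% lineage
  if (!is.null(source)) keep <- keep & table$samples$source %in% source
  if (!is.null(unit_id)) keep <- keep & table$samples$unit_id %in% unit_id
  which(keep)
}

#' Proteins detected under a presence rule
#'
#' @param table a [protein_quant_table()].
#' @param rule a [presence_rule()].
#' @param name name for the resulting set.
#' @return An [accession_set()] of proteins detected in enough scoped samples.
#' @export
presence_set <- function(table, rule, name = NULL) {
  idx <- select_samples(table, rule$lineage, rule$source, rule$unit_id)
  if (length(idx) == 0L) {
    stop("presence rule scope selects zero samples", call. = FALSE)
  }
  if (rule$mode == "at_least_k" && rule$k > length(idx)) {
    stop("k = ", rule$k, " exceeds the ", length(idx),
         " samples in scope", call. = FALSE)
  }
  need <- if (rule$mode == "all") length(idx) else rule$k
  detected <- rowSums(table$intensities[, idx, drop = FALSE] > 0)
  if (is.null(name)) {
    name <- paste(c(rule$lineage, rule$source, rule$unit_id, rule$mode),
                  collapse = "_")
  }
  accession_set(name, table$accessions[detected >= need])
}

#' Combine per-unit presence sets
#'
#' Aggregates per-cell-line (or per-explant) presence sets into one
#' lineage-source set, by union (a protein robustly detected in any one unit
#' counts) or intersection.
#'
#' @param sets list of [accession_set()] objects, at least one.
#' @param combine `"union"` or `"intersection"`.
#' @param name optional name; default records the combine mode.
#' @return An [accession_set()].
#' @export
combine_presence <- function(sets, combine = c("union", "intersection"),
                             name = NULL) {
  combine <- match.arg(combine)
  if (length(sets) == 0L) stop("need at least one input set", call. = FALSE)
  members <- lapply(sets, `[[`, "members")
  out <- Reduce(if (combine == "union") union else intersect, members)
  if (is.null(name)) {
    name <- paste0(combine, "(", paste(vapply(sets, `[[`, "", "name"),
                                       collapse = ","), ")")
  }
  accession_set(name, out)
}

#' Lineage consensus: proteins shared by tissue-explant and cell-line EVs
#'
#' Intersecting the tissue-derived set with the matched cell-line set keeps
#' proteins specific to the lineage's site of origin.
#'
#' @param tissue_set,cellline_set non-empty [accession_set()] objects.
#' @param lineage label used to name the result (`"<lineage>_consensus"`).
#' @return An [accession_set()].
#' @export
lineage_consensus <- function(tissue_set, cellline_set, lineage = "lineage") {
  if (length(tissue_set$members) == 0L || length(cellline_set$members) == 0L) {
    stop("both input sets must be non-empty", call. = FALSE)
  }
  out <- accession_set(paste0(lineage, "_consensus"),
                       intersect(tissue_set$members, cellline_set$members))
  if (length(out$members) == 0L) {
    warning("lineage consensus for ", lineage, " is empty", call. = FALSE)
  }
  out
}

#' Core proteome: proteins common to both lineages
#'
#' @param hgsoc,ft non-empty [accession_set()] objects (lineage consensus
#'   sets).
#' @return An [accession_set()] named `"FT/HGSOC_core"`.
#' @export
core_proteome <- function(hgsoc, ft) {
  if (length(hgsoc$members) == 0L || length(ft$members) == 0L) {
    stop("both input sets must be non-empty", call. = FALSE)
  }
  out <- accession_set("FT/HGSOC_core", intersect(hgsoc$members, ft$members))
  if (length(out$members) == 0L) {
    warning("core proteome is empty", call. = FALSE)
  }
  out
}

#' Intersect candidates with an annotation list
#'
#' Used to restrict the core proteome to known or predicted transmembrane
#' proteins, which can serve as antigens for immunocapture or detection.
#'
#' @param core,annotation [accession_set()] objects.
#' @return An [accession_set()].
#' @export
intersect_annotation <- function(core, annotation) {
  accession_set(paste0(core$name, "&", annotation$name),
                intersect(core$members, annotation$members))
}

#' Subtract common EV proteins
#'
#' Removes candidates appearing in curated lists of ubiquitously observed EV
#' proteins (e.g. the ExoCarta / Vesiclepedia top-100 lists).
#'
#' @param candidates an [accession_set()].
#' @param common_lists list of [accession_set()] objects (possibly empty).
#' @return An [accession_set()].
#' @export
subtract_common_ev <- function(candidates, common_lists = list()) {
  common <- unique(unlist(lapply(common_lists, `[[`, "members")))
  accession_set(paste0(candidates$name, "-common_ev"),
                setdiff(candidates$members, common))
}

#' Log2 fold change between two sample groups
#'
#' `log2((mean_a + pseudocount) / (mean_b + pseudocount))` with arithmetic
#' group means of the table's intensities. In pipeline use the table is
#' per-sample normalized first and group A is HGSOC, group B is FT, so
#' positive values mean higher abundance in carcinoma-derived EVs.
#'
#' @param table a [protein_quant_table()].
#' @param accession protein accession present in the table.
#' @param group_a,group_b scope selector lists with elements `lineage`,
#'   `source`, `unit_id` (each optional), passed to the sample selector.
#' @param pseudocount non-negative value added to both means to keep
#'   presence/absence proteins finite.
#' @return A single numeric log2 fold change.
#' @export
log2_fold_change <- function(table, accession, group_a, group_b,
                             pseudocount = 0) {
  if (!accession %in% table$accessions) {
    stop("accession '", accession, "' not in table", call. = FALSE)
  }
  ia <- do.call(select_samples, c(list(table), group_a))
  ib <- do.call(select_samples, c(list(table), group_b))
  if (length(ia) == 0L || length(ib) == 0L) {
    stop("fold-change group selector matches no samples", call. = FALSE)
  }
  x <- table$intensities[accession, ]
  log2((mean(x[ia]) + pseudocount) / (mean(x[ib]) + pseudocount))
}

#' Filter candidates by fold change and rank
#'
#' Keeps accessions with log2 fold change at or above `threshold` and returns
#' them sorted by decreasing fold change (ties broken by accession order for
#' determinism).
#'
#' @param candidates an [accession_set()].
#' @param fold_changes named numeric vector, accession -> log2FC, covering
#'   every candidate.
#' @param threshold minimum log2 fold change (default -0.58, retaining
#'   proteins present in benign fallopian-tube EVs whose abundance is stable
#'   or increases with disease).
#' @return Character vector of ranked accessions.
#' @export
fc_filter_and_rank <- function(candidates, fold_changes, threshold = -0.58) {
  missing_fc <- setdiff(candidates$members, names(fold_changes))
  if (length(missing_fc) > 0L) {
    stop("no fold change for candidate(s): ",
         paste(missing_fc, collapse = ", "), call. = FALSE)
  }
  fc <- fold_changes[candidates$members]
  keep <- names(fc)[fc >= threshold]
  keep[order(-fc[keep], keep)]
}

#' Remove manually excluded accessions from a ranked list
#'
#' For candidates known from the literature to be common EV proteins despite
#' not appearing in the curated lists.
#'
#' @param ranked character vector (ranked accessions).
#' @param exclusions an [accession_set()] or character vector.
#' @return The ranked list minus the exclusions, order preserved.
#' @export
manual_exclude <- function(ranked, exclusions) {
  excl <- if (inherits(exclusions, "accession_set")) exclusions$members
          else as.character(exclusions)
  absent <- setdiff(excl, ranked)
  if (length(absent) > 0L) {
    warning("exclusion(s) not present in ranked list: ",
            paste(absent, collapse = ", "), call. = FALSE)
  }
  ranked[!ranked %in% excl]
}

#' Per-sample relative abundance in parts per million
#'
#' Divides each sample column by its total intensity and scales to ppm, so
#' abundances are comparable across runs with different total ion current.
#'
#' @param table a [protein_quant_table()].
#' @return A [protein_quant_table()] whose columns each sum to 1e6.
#' @export
relative_abundance <- function(table) {
  totals <- colSums(table$intensities)
  zero <- totals <= 0
  if (any(zero)) {
    stop("sample(s) with zero total intensity: ",
         paste(table$samples$sample_id[zero], collapse = ", "), call. = FALSE)
  }
  norm <- sweep(table$intensities, 2, totals, "/") * 1e6
  protein_quant_table(norm, table$samples)
}

#' Immunohistochemistry H-score
#'
#' Intensity-weighted sum of stained-area percentages:
#' `0*pct0 + 1*pct1 + 2*pct2 + 3*pct3`, ranging 0 (no staining) to 300
#' (uniform strong staining). Percentages must sum to 100.
#'
#' @param pct0,pct1,pct2,pct3 percentages of cell area with absent, weak
#'   (1+), moderate (2+) and strong (3+) staining.
#' @return H-score in \[0, 300\].
#' @export
h_score <- function(pct0, pct1, pct2, pct3) {
  p <- c(pct0, pct1, pct2, pct3)
  if (any(p < 0) || any(p > 100)) {
    stop("area percentages must lie in [0, 100]", call. = FALSE)
  }
  if (abs(sum(p) - 100) > 1e-9) {
    stop("area percentages must sum to 100 (got ", sum(p), ")", call. = FALSE)
  }
  sum(p * 0:3)
}

#' Default presence rules for the candidate funnel
#'
#' Inclusion criteria per sample group: HGSOC cell lines require detection in
#' at least two of three biological replicates, FT cell lines in both
#' replicates, and tissue explants in all replicates of their set.
#'
#' @return Named list of [presence_rule()] objects keyed `"lineage.source"`.
#' @export
default_presence_rules <- function() {
  list(
    HGSOC.cell_line = presence_rule(mode = "at_least_k", k = 2L),
    FT.cell_line = presence_rule(mode = "all"),
    HGSOC.tissue = presence_rule(mode = "all"),
    FT.tissue = presence_rule(mode = "all")
  )
}

group_presence <- function(table, lineage, source, rule, combine) {
  units <- unique(table$samples$unit_id[select_samples(table, lineage, source)])
  if (length(units) == 0L) {
    stop("no samples for ", lineage, " ", source, call. = FALSE)
  }
  per_unit <- lapply(units, function(u) {
    r <- presence_rule(lineage = lineage, source = source, unit_id = u,
                       mode = rule$mode, k = rule$k)
    presence_set(table, r)
  })
  combine_presence(per_unit, combine, name = paste(lineage, source, sep = "_"))
}

#' Run the full candidate-prioritization funnel
#'
#' Executes the fixed stage order: per-group presence filtering, per-lineage
#' tissue/cell-line consensus, core proteome, transmembrane-annotation
#' intersection, common-EV subtraction, fold-change filtering and ranking,
#' and manual exclusion. Intensities are per-sample normalized (ppm) before
#' fold changes; the fold-change pseudocount defaults to half the smallest
#' nonzero normalized intensity.
#'
#' @param table a [protein_quant_table()].
#' @param tm_list [accession_set()] of known/predicted transmembrane proteins.
#' @param common_lists list of [accession_set()] common-EV lists.
#' @param exclusions optional [accession_set()] of manual exclusions.
#' @param rules named list of [presence_rule()]s keyed `"lineage.source"`
#'   (see [default_presence_rules()]).
#' @param fc_threshold log2 fold-change cutoff (default -0.58).
#' @param fc_scope samples used for the fold-change group means: `"pooled"`
#'   (tissue + cell line, default), `"tissue"` or `"cell_line"`.
#' @param combine how per-unit presence sets merge into a lineage-source set
#'   (default `"union"`).
#' @param pseudocount override for the fold-change pseudocount.
#' @return An object of class `candidate_funnel`: `stages` (ordered list of
#'   `(name, set, count)`), `fold_changes` (named vector over the common-EV
#'   subtracted candidates) and `final_ranked`.
#' @export
run_funnel <- function(table, tm_list, common_lists = list(),
                       exclusions = NULL, rules = default_presence_rules(),
                       fc_threshold = -0.58,
                       fc_scope = c("pooled", "tissue", "cell_line"),
                       combine = c("union", "intersection"),
                       pseudocount = NULL) {
  fc_scope <- match.arg(fc_scope)
  combine <- match.arg(combine)
  norm <- relative_abundance(table)
  stages <- list()
  add_stage <- function(set, stage_name = set$name) {
    stages[[length(stages) + 1L]] <<- list(name = stage_name, set = set,
                                           count = length(set$members))
    set
  }
  group_sets <- list()
  for (lineage in c("HGSOC", "FT")) {
    for (source in c("tissue", "cell_line")) {
      key <- paste(lineage, source, sep = ".")
      rule <- rules[[key]]
      if (is.null(rule)) stop("no presence rule for ", key, call. = FALSE)
      group_sets[[key]] <- add_stage(
        group_presence(table, lineage, source, rule, combine))
    }
  }
  hgsoc <- add_stage(lineage_consensus(group_sets[["HGSOC.tissue"]],
                                       group_sets[["HGSOC.cell_line"]],
                                       "HGSOC"))
  ft <- add_stage(lineage_consensus(group_sets[["FT.tissue"]],
                                    group_sets[["FT.cell_line"]], "FT"))
  core <- add_stage(core_proteome(hgsoc, ft), "core")
  tm <- add_stage(intersect_annotation(core, tm_list), "transmembrane")
  cand <- add_stage(subtract_common_ev(tm, common_lists), "minus_common_ev")
  src_scope <- switch(fc_scope, pooled = NULL, tissue = "tissue",
                      cell_line = "cell_line")
  if (is.null(pseudocount)) {
    pos <- norm$intensities[norm$intensities > 0]
    pseudocount <- if (length(pos)) min(pos) / 2 else 0
  }
  fc <- vapply(cand$members, function(a) {
    log2_fold_change(norm, a,
                     group_a = list(lineage = "HGSOC", source = src_scope),
                     group_b = list(lineage = "FT", source = src_scope),
                     pseudocount = pseudocount)
  }, numeric(1))
  ranked <- fc_filter_and_rank(cand, fc, fc_threshold)
  add_stage(accession_set("fc_pass", ranked))
  final <- if (is.null(exclusions) || length(exclusions) == 0L) ranked
           else manual_exclude(ranked, exclusions)
  final_set <- accession_set("final", final)
  stages[[length(stages) + 1L]] <- list(name = "final", set = final_set,
                                        count = length(final))
  structure(
    list(stages = stages, fold_changes = fc,
         final_ranked = final[order(-fc[final], final)],
         config = list(fc_threshold = fc_threshold, fc_scope = fc_scope,
                       combine = combine, pseudocount = pseudocount)),
    class = "candidate_funnel"
  )
}

#' Stage counts of a candidate funnel
#' @param funnel a `candidate_funnel`.
#' @return Named integer vector of stage sizes in stage order.
#' @export
funnel_counts <- function(funnel) {
  stats::setNames(vapply(funnel$stages, `[[`, 0L, "count"),
                  vapply(funnel$stages, `[[`, "", "name"))
}

#' @export
print.candidate_funnel <- function(x, ...) {
  cat("Candidate funnel:\n")
  for (s in x$stages) cat(sprintf("  %-22s %5d\n", s$name, s$count))
  invisible(x)
}
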