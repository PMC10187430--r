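#' Configuration for a simulated EV proteome experiment
#'
#' Describes a label-free quantification experiment with planted protein
#' classes whose fate in the candidate funnel is known in advance, so funnel
#' stage counts become exact test oracles. Within their defining sample
#' groups the planted classes are present with probability 1; intensities
#' are log-normal. Fold-change classes multiply the HGSOC-sample mean by
#' `fc_shift`, so the keep class sits comfortably above the default
#' log2 fold-change cutoff of -0.58 and the fail class comfortably below it.
#'
#' @param groups data.frame with columns `lineage`, `source`, `n_units`,
#'   `n_replicates`; defaults emulate the study design (three HGSOC cell
#'   lines with triplicate EV isolations, two FT cell lines in duplicate,
#'   and tissue explants per lineage).
#' @param classes named integer vector of planted class counts:
#'   `core_tm_keep` (survive the full funnel), `core_tm_fc_fail`
#'   (transmembrane core proteins failing the fold-change cut),
#'   `core_common_ev` (transmembrane but on the common-EV lists),
#'   `core_non_tm` (core proteome, not transmembrane), `hgsoc_only`,
#'   `ft_only`, `absent`.
#' @param meanlog,sdlog log-normal intensity parameters (per-sample noise).
#' @param fc_shift named multiplicative HGSOC/FT mean ratios per class.
#' @param seed RNG seed.
#' @return A `proteome_sim_config` list.
#' @export
proteome_sim_config <- function(
    groups = data.frame(
      lineage = c("HGSOC", "FT", "HGSOC", "FT"),
      source = c("cell_line", "cell_line", "tissue", "tissue"),
      n_units = c(3L, 2L, 3L, 3L),
      n_replicates = c(3L, 2L, 2L, 2L)
    ),
    classes = c(core_tm_keep = 30L, core_tm_fc_fail = 10L,
                core_common_ev = 5L, core_non_tm = 40L,
                hgsoc_only = 15L, ft_only = 15L, absent = 5L),
    meanlog = log(1e6), sdlog = 0.3,
    fc_shift = c(core_tm_keep = 2, core_tm_fc_fail = 0.25),
    seed = 1L) {
  needed <- c("core_tm_keep", "core_tm_fc_fail", "core_common_ev",
              "core_non_tm", "hgsoc_only", "ft_only", "absent")
  missing_cls <- setdiff(needed, names(classes))
  if (length(missing_cls) > 0L) {
    stop("classes missing: ", paste(missing_cls, collapse = ", "),
         call. = FALSE)
  }
  if (any(classes < 0)) stop("class counts must be non-negative", call. = FALSE)
  structure(list(groups = groups, classes = classes, meanlog = meanlog,
                 sdlog = sdlog, fc_shift = fc_shift, seed = as.integer(seed)),
            class = "proteome_sim_config")
}

#' Simulate an EV proteome quantification experiment with ground truth
#'
#' Deterministic for a given config (the seed is part of the config, and no
#' global RNG state is consumed or leaked). Planted classes are realized with
#' presence probability 1 inside their defining groups and absence (zero
#' intensity) outside them, so the expected funnel stage counts in the
#' returned truth are exact, not stochastic.
#'
#' @param config a [proteome_sim_config()].
#' @return List with `table` (a [protein_quant_table()]), `tm_list`,
#'   `common_ev` and `exclusions` ([accession_set()]s), and `truth` (planted
#'   class per accession plus expected funnel stage counts).
#' @export
simulate_proteome <- function(config = proteome_sim_config()) {
  cl <- config$classes
  withr::with_seed(config$seed, {
    meta <- do.call(rbind, lapply(seq_len(nrow(config$groups)), function(i) {
      g <- config$groups[i, ]
      units <- sprintf("%s_%s_U%d", g$lineage,
                       ifelse(g$source == "cell_line", "CL", "TX"),
                       seq_len(g$n_units))
      do.call(rbind, lapply(units, function(u) {
        data.frame(sample_id = sprintf("%s_R%d", u, seq_len(g$n_replicates)),
                   lineage = g$lineage, source = g$source, unit_id = u,
                   replicate = seq_len(g$n_replicates),
                   stringsAsFactors = FALSE)
      }))
    }))
    n_prot <- sum(cl)
    acc <- sprintf("SYN%04d", seq_len(n_prot))
    class_of <- rep(names(cl), cl)
    is_hgsoc <- meta$lineage == "HGSOC"
    base <- stats::rlnorm(n_prot, config$meanlog, config$sdlog)
    mat <- matrix(0, n_prot, nrow(meta), dimnames = list(acc, meta$sample_id))
    for (i in seq_len(n_prot)) {
      k <- class_of[i]
      if (k == "absent") next
      present <- if (k == "hgsoc_only") is_hgsoc
                 else if (k == "ft_only") !is_hgsoc
                 else rep(TRUE, nrow(meta))
      shift <- config$fc_shift[k]
      if (is.na(shift)) shift <- 1
      mult <- ifelse(is_hgsoc, shift, 1)
      vals <- base[i] * mult * stats::rlnorm(nrow(meta), 0, config$sdlog)
      mat[i, present] <- vals[present]
    }
    table <- protein_quant_table(mat, meta)
    tm_members <- acc[class_of %in% c("core_tm_keep", "core_tm_fc_fail",
                                      "core_common_ev")]
    common_members <- acc[class_of == "core_common_ev"]
    n_core <- sum(cl[c("core_tm_keep", "core_tm_fc_fail", "core_common_ev",
                       "core_non_tm")])
    expected <- c(
      HGSOC_consensus = unname(n_core + cl["hgsoc_only"]),
      FT_consensus = unname(n_core + cl["ft_only"]),
      core = unname(n_core),
      transmembrane = unname(cl["core_tm_keep"] + cl["core_tm_fc_fail"] +
                               cl["core_common_ev"]),
      minus_common_ev = unname(cl["core_tm_keep"] + cl["core_tm_fc_fail"]),
      fc_pass = unname(cl["core_tm_keep"]),
      final = unname(cl["core_tm_keep"])
    )
    list(
      table = table,
      tm_list = accession_set("transmembrane_synthetic", tm_members),
      common_ev = accession_set("common_ev_synthetic", common_members),
      exclusions = accession_set("exclusions_synthetic", character(0)),
      truth = list(accession = acc, class = class_of,
                   expected_counts = expected, seed = config$seed)
    )
  })
}

#' Configuration for simulated case/control marker scores
#'
#' Each marker is drawn from a stated generative shape on the log-score
#' scale: `binormal` (controls N(0,1), cases N(delta,1) with
#' `delta = sqrt(2) * qnorm(target_auc)` so the true AUC is `target_auc`),
#' `separated` (cases N(10,1); complete separation), `bimodal` (cases an
#' equal mixture of N(-delta_b,1) and N(+delta_b,1) straddling the controls:
#' a non-monotone marker with AUC near 0.5), and `null` (both groups
#' N(0,1)).
#'
#' @param n_cases,n_controls group sizes (defaults 10 and 20, the chip
#'   cohort design).
#' @param markers data.frame with columns `name`, `shape`, `target_auc`,
#'   `delta_b`.
#' @param seed RNG seed.
#' @return A `marker_sim_config` list.
#' @export
marker_sim_config <- function(
    n_cases = 10L, n_controls = 20L,
    markers = data.frame(name = c("M1", "M2"),
                         shape = c("binormal", "null"),
                         target_auc = c(0.9, NA), delta_b = NA,
                         stringsAsFactors = FALSE),
    seed = 1L) {
  if (n_cases < 2L || n_controls < 2L) {
    stop("need at least 2 subjects per group", call. = FALSE)
  }
  bad <- setdiff(markers$shape, c("binormal", "separated", "bimodal", "null"))
  if (length(bad) > 0L) {
    stop("unknown marker shape(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  bn <- markers$shape == "binormal"
  if (any(bn & (is.na(markers$target_auc) | markers$target_auc <= 0.5 |
                  markers$target_auc >= 1))) {
    stop("binormal markers need target_auc in (0.5, 1)", call. = FALSE)
  }
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 markers = markers, seed = as.integer(seed)),
            class = "marker_sim_config")
}

#' Binormal mean shift achieving a target AUC
#'
#' For equal-variance normal groups N(0,1) vs N(delta,1) the AUC is
#' `pnorm(delta / sqrt(2))`, so `delta = sqrt(2) * qnorm(target_auc)`.
#'
#' @param target_auc AUC in (0.5, 1).
#' @return The mean shift delta.
#' @export
binormal_delta <- function(target_auc) sqrt(2) * stats::qnorm(target_auc)

#' Simulate case/control marker scores with ground truth
#'
#' @param config a [marker_sim_config()].
#' @return List with `table` (a [marker_score_table()]; values on the raw
#'   fluorescence-like scale `10^(3 + z/2)` with a constant-scale background
#'   channel, so that [preprocess_scores()] recovers the generative log-scale
#'   scores up to an affine map) and `truth` (per-marker shape, delta and
#'   true AUC, plus the log-scale scores).
#' @export
simulate_markers <- function(config = marker_sim_config()) {
  withr::with_seed(config$seed, {
    n <- config$n_cases + config$n_controls
    labels <- c(rep("case", config$n_cases), rep("control", config$n_controls))
    z <- matrix(NA_real_, n, nrow(config$markers),
                dimnames = list(NULL, config$markers$name))
    truth <- list()
    for (j in seq_len(nrow(config$markers))) {
      mk <- config$markers[j, ]
      ctrl <- stats::rnorm(config$n_controls)
      if (mk$shape == "binormal") {
        delta <- binormal_delta(mk$target_auc)
        case <- stats::rnorm(config$n_cases, mean = delta)
        true_auc <- mk$target_auc
      } else if (mk$shape == "separated") {
        delta <- 10
        case <- stats::rnorm(config$n_cases, mean = delta)
        true_auc <- stats::pnorm(delta / sqrt(2))
      } else if (mk$shape == "bimodal") {
        delta <- if (is.na(mk$delta_b)) 3 else mk$delta_b
        side <- sample(c(-1, 1), config$n_cases, replace = TRUE)
        case <- stats::rnorm(config$n_cases, mean = side * delta)
        true_auc <- 0.5
      } else {
        delta <- 0
        case <- stats::rnorm(config$n_cases)
        true_auc <- 0.5
      }
      z[, j] <- c(case, ctrl)
      truth[[mk$name]] <- list(shape = mk$shape, delta = delta,
                               true_auc = true_auc)
    }
    subjects <- data.frame(
      subject_id = sprintf("SUBJ%03d", seq_len(n)),
      label = labels, stringsAsFactors = FALSE)
    raw <- 10^(3 + z / 2)
    background <- stats::rlnorm(n, log(20), 0.1)
    table <- marker_score_table(subjects, raw, background)
    list(table = table,
         truth = list(markers = truth, log_scores = z, labels = labels,
                      seed = config$seed))
  })
}

#' Write a ready-to-run synthetic fixture to disk
#'
#' Presets: `"funnel_small"` writes a quantification matrix, sample
#' metadata, transmembrane and common-EV accession lists and a `truth.json`
#' with the expected funnel stage counts; `"markers_paperlike"` writes a
#' 30-subject score CSV (10 cases, 20 controls) with seven binormal markers
#' named after the chip panel, with per-marker target AUCs, plus
#' `truth.json`.
#'
#' @param out_dir output directory (created if needed).
#' @param preset `"funnel_small"` or `"markers_paperlike"`.
#' @param seed RNG seed.
#' @return Named character vector of the files written, invisibly.
#' @export
make_fixture <- function(out_dir, preset = c("funnel_small",
                                             "markers_paperlike"),
                         seed = 1L) {
  preset <- match.arg(preset)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (preset == "funnel_small") {
    sim <- simulate_proteome(proteome_sim_config(seed = seed))
    files <- c(matrix = file.path(out_dir, "quant_matrix.tsv"),
               meta = file.path(out_dir, "sample_meta.tsv"),
               tm = file.path(out_dir, "transmembrane.txt"),
               common_ev = file.path(out_dir, "common_ev_top100.txt"),
               truth = file.path(out_dir, "truth.json"))
    write_quant_table(sim$table, files["matrix"], files["meta"])
    write_accession_list(sim$tm_list, files["tm"])
    write_accession_list(sim$common_ev, files["common_ev"])
    jsonlite::write_json(
      list(preset = preset, seed = seed,
           class = stats::setNames(as.list(sim$truth$class),
                                   sim$truth$accession),
           expected_counts = as.list(sim$truth$expected_counts)),
      files["truth"], auto_unbox = TRUE, digits = NA)
  } else {
    panel <- data.frame(
      name = c("ACSL4", "IGSF8", "ITGA2", "ITGA5", "ITGB3", "MYOF", "FOLR1"),
      shape = "binormal",
      target_auc = c(0.915, 0.895, 0.885, 0.95, 0.98, 0.85, 0.925),
      delta_b = NA, stringsAsFactors = FALSE)
    sim <- simulate_markers(marker_sim_config(n_cases = 10L, n_controls = 20L,
                                              markers = panel, seed = seed))
    files <- c(scores = file.path(out_dir, "scores.csv"),
               truth = file.path(out_dir, "truth.json"))
    write_score_table(sim$table, files["scores"])
    jsonlite::write_json(
      list(preset = preset, seed = seed,
           markers = sim$truth$markers),
      files["truth"], auto_unbox = TRUE, digits = NA)
  }
  invisible(files)
}
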