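# Cohort-level orchestration: sample-sheet QC accounting, the CMV
# serostatus association check, and the end-to-end simulate -> diversity ->
# MDS -> classify driver with per-stage derived seeds and a manifest.

qc_exclusion_reasons <- c("insufficient_cells", "cross_contamination",
                          "insufficient_dna", "library_failure")

#' The study cohort's sample sheet with printed QC exclusion tallies
#'
#' Reconstructs the per-(sample, cell type) sheet of the 160-donor cohort:
#' four groups of 40 female donors with the published age-bin structure,
#' both CD4 and CD8 enrichments per donor, the published exclusion tallies
#' (CD8: one insufficient-cells, five cross-contaminated; CD4: two
#' insufficient-cells, four insufficient-DNA, six library failures) and the
#' published CMV serostatus counts per group (98 of 160 donors assayed).
#' Which individual donors were excluded is not published, so exclusions
#' and serostatus are assigned to donors deterministically within groups;
#' all aggregate tallies match the published ones.
#'
#' @return tibble with columns `sample_id`, `donor_id`, `group`,
#'   `cell_type`, `age_bin`, `cmv_status`, `qc_status`.
#' @export
study_sample_sheet <- function() {
  groups <- c("MEsa", "MEmm", "MS", "HC")
  age_tab <- list(  # donors per age bin, by group
    MEsa = c(`18-29` = 8, `30-39` = 9, `40-49` = 6, `50-60` = 17),
    MEmm = c(`18-29` = 0, `30-39` = 0, `40-49` = 20, `50-60` = 20),
    MS   = c(`18-29` = 0, `30-39` = 0, `40-49` = 12, `50-60` = 28),
    HC   = c(`18-29` = 0, `30-39` = 1, `40-49` = 16, `50-60` = 23))
  cmv_tab <- list(  # Positive / Negative / Equivocal donors per group
    MEsa = c(Positive = 14, Negative = 19, Equivocal = 2),
    MEmm = c(Positive = 4,  Negative = 9,  Equivocal = 0),
    MS   = c(Positive = 11, Negative = 14, Equivocal = 0),
    HC   = c(Positive = 12, Negative = 13, Equivocal = 0))
  donors <- dplyr::bind_rows(lapply(groups, function(g) {
    ages <- rep(names(age_tab[[g]]), times = age_tab[[g]])
    cmv <- rep(names(cmv_tab[[g]]), times = cmv_tab[[g]])
    cmv <- c(cmv, rep(NA_character_, 40L - length(cmv)))
    tibble::tibble(donor_id = sprintf("%s_d%02d", g, seq_len(40L)),
                   group = g, age_bin = ages, cmv_status = cmv)
  }))
  # published exclusion tallies, assigned to the leading donors of each list
  qc_cd8 <- rep("pass", 160L)
  qc_cd8[1L] <- "insufficient_cells"
  qc_cd8[2:6] <- "cross_contamination"
  qc_cd4 <- rep("pass", 160L)
  qc_cd4[1:2] <- "insufficient_cells"
  qc_cd4[3:6] <- "insufficient_dna"
  qc_cd4[7:12] <- "library_failure"
  dplyr::bind_rows(
    dplyr::mutate(donors, cell_type = "CD8", qc_status = qc_cd8,
                  sample_id = paste0(donor_id, "_CD8")),
    dplyr::mutate(donors, cell_type = "CD4", qc_status = qc_cd4,
                  sample_id = paste0(donor_id, "_CD4")))
}

#' Apply QC exclusions to a sample sheet
#'
#' Splits the sheet into retained and excluded rows, binning exclusions by
#' reason per cell type. Retained plus excluded always equals the input.
#'
#' @param sheet tibble with at least `sample_id`, `cell_type`, `qc_status`
#'   (`"pass"` or one of the exclusion reason codes).
#' @return list with `retained` (sheet subset), `excluded`, and `report`
#'   (tibble per cell type: input, per-reason exclusion counts, retained).
#' @export
apply_qc_exclusions <- function(sheet) {
  bad <- setdiff(unique(sheet$qc_status), c("pass", qc_exclusion_reasons))
  if (length(bad) > 0L)
    stop("unknown QC reason code(s): ", paste(bad, collapse = ", "))
  keep <- sheet$qc_status == "pass"
  report <- dplyr::bind_rows(lapply(unique(sheet$cell_type), function(ct) {
    rows <- sheet[sheet$cell_type == ct, , drop = FALSE]
    counts <- vapply(qc_exclusion_reasons,
                     function(r) sum(rows$qc_status == r), integer(1))
    tibble::tibble(cell_type = ct, n_input = nrow(rows),
                   !!!as.list(counts),
                   n_retained = sum(rows$qc_status == "pass"))
  }))
  list(retained = sheet[keep, , drop = FALSE],
       excluded = sheet[!keep, , drop = FALSE],
       report = report)
}

#' Chi-squared test of CMV serostatus against sample group
#'
#' Pearson test of independence on the serostatus x group contingency
#' table built from one row per donor, dropping donors without a serostatus
#' and any all-zero rows or columns (with a warning). No continuity
#' correction is applied (none exists for r x c tables beyond 2 x 2).
#'
#' @param sheet a sample sheet with `donor_id`, `group`, `cmv_status`.
#' @return list with `statistic`, `df`, `p_value` and the contingency
#'   `table`.
#' @export
cmv_association_test <- function(sheet) {
  donors <- sheet[!duplicated(sheet$donor_id), , drop = FALSE]
  donors <- donors[!is.na(donors$cmv_status), , drop = FALSE]
  tab <- table(donors$cmv_status, donors$group)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("dropping empty serostatus rows/columns before testing")
    tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  }
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop("need at least two serostatus categories and two groups")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value, table = tab)
}

#' Configuration for an end-to-end simulated run
#'
#' @param seed master seed; every stage derives its own stream from it.
#' @param groups named vector of group sizes.
#' @param base_expansion,effect_delta,effect_groups,depth_range,expansion_shape
#'   cohort parameters (see [cohort_spec()]).
#' @param cell_types,chains combinations to simulate and analyse.
#' @param grid [alpha_grid()] for the diversity profiles.
#' @param n_perm permutations per comparison.
#' @param mds_dims MDS dimensions to record.
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1L, groups = c(A = 10, B = 10),
                       base_expansion = 0.05, effect_delta = 0,
                       effect_groups = NULL, depth_range = c(1e3, 1e4),
                       expansion_shape = 0.2, cell_types = "CD8",
                       chains = "beta", grid = alpha_grid(),
                       n_perm = 199L, mds_dims = 2L) {
  if (length(groups) < 2L) stop("need at least two groups")
  if (!all(chains %in% c("alpha", "beta", "gamma")))
    stop("unknown chain: ", paste(setdiff(chains, c("alpha", "beta", "gamma")),
                                  collapse = ", "))
  structure(list(seed = as.integer(seed), groups = groups,
                 base_expansion = base_expansion,
                 effect_delta = effect_delta,
                 effect_groups = effect_groups,
                 depth_range = depth_range,
                 expansion_shape = expansion_shape,
                 cell_types = cell_types, chains = chains, grid = grid,
                 n_perm = as.integer(n_perm), mds_dims = as.integer(mds_dims)),
            class = "run_config")
}

#' Run the simulated pipeline end to end
#'
#' For every (cell type, chain) combination: simulates a cohort under the
#' config, computes the depth-equalised profile-distance matrix, embeds it
#' with classical MDS, and permutation-tests the P-SVM separation of every
#' group pair. All randomness derives from the master seed by stage name,
#' so a rerun with the same config is identical; when `out_dir` is given,
#' the distance matrices, MDS coordinates, classification report and a
#' manifest are written beneath it.
#'
#' @param config a [run_config()].
#' @param out_dir optional output directory.
#' @return list with `metadata`, `dist_matrices`, `embeddings`, `report`
#'   (tibble of pairwise group comparisons), and `paths` when written.
#' @export
run_all <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  dist_matrices <- list(); embeddings <- list(); metadata <- list()
  report <- list(); paths <- character(0)
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  for (ct in config$cell_types) {
    for (ch in config$chains) {
      key <- paste(ct, ch, sep = "_")
      cs <- cohort_spec(groups = config$groups,
                        base_expansion = config$base_expansion,
                        effect_delta = config$effect_delta,
                        effect_groups = config$effect_groups,
                        depth_range = config$depth_range,
                        expansion_shape = config$expansion_shape,
                        cell_type = ct, chain = ch,
                        seed = derive_seed(config$seed, "simulate", key))
      cohort <- simulate_cohort(cs)
      metadata[[key]] <- cohort[, c("sample_id", "group", "cell_type",
                                    "chain", "depth")]
      D <- distance_matrix(cohort_counts(cohort), grid = config$grid,
                           seed = derive_seed(config$seed, "distance", key))
      dist_matrices[[key]] <- D
      embeddings[[key]] <- classical_mds(D, k = config$mds_dims)
      groups <- names(config$groups)
      for (i in seq_len(length(groups) - 1L)) {
        for (k in seq(i + 1L, length(groups))) {
          ga <- groups[i]; gb <- groups[k]
          ids_a <- cohort$sample_id[cohort$group == ga]
          ids_b <- cohort$sample_id[cohort$group == gb]
          ids <- c(ids_a, ids_b)
          y <- c(rep(1, length(ids_a)), rep(-1, length(ids_b)))
          res <- permutation_test(
            D[ids, ids], y, n_perm = config$n_perm,
            seed = derive_seed(config$seed, "classify", key, ga, gb),
            comparison = sprintf("%s vs %s [%s]", ga, gb, key))
          report[[length(report) + 1L]] <- tibble::tibble(
            cell_type = ct, chain = ch, comparison = paste(ga, "vs", gb),
            observed = res$observed, p_value = res$p_value,
            n_perm = res$n_perm, truncated = res$truncated)
        }
      }
      if (!is.null(out_dir)) {
        p1 <- file.path(out_dir, paste0("distances_", key, ".tsv"))
        write_distance_matrix(D, p1)
        p2 <- file.path(out_dir, paste0("mds_", key, ".tsv"))
        write_embedding(embeddings[[key]], coords_path = p2)
        p3 <- file.path(out_dir, paste0("samples_", key, ".tsv"))
        utils::write.table(metadata[[key]], p3, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        paths <- c(paths, p1, p2, p3)
      }
    }
  }
  report <- dplyr::bind_rows(report)
  if (!is.null(out_dir)) {
    rp <- file.path(out_dir, "classification_report.tsv")
    utils::write.table(report, rp, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    manifest <- list(seed = config$seed,
                     groups = as.list(config$groups),
                     effect_delta = config$effect_delta,
                     n_perm = config$n_perm,
                     grid = range(as.numeric(config$grid)),
                     files = basename(c(paths, rp)))
    mp <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE)
    paths <- c(paths, rp, mp)
  }
  list(metadata = dplyr::bind_rows(metadata), dist_matrices = dist_matrices,
       embeddings = embeddings, report = report, paths = paths)
}
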