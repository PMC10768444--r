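# Simulation of clonally structured repertoires and multi-sample cohorts.
#
# A sample's clone-size structure is a mixture of singleton clonotypes
# (most TCR sequences are seen once) and a minority of expanded clones
# whose sizes follow a shifted, truncated geometric law
# P(S = k) = q (1-q)^(k-2), k >= 2 -- a single-parameter heavy tail with a
# closed-form pmf, convenient for goodness-of-fit testing. The expanded
# fraction is the knob a disease effect turns.

#' Specification of one simulated repertoire
#'
#' @param n_clonotypes clonotype budget used to size the expanded class
#'   (`n_expanded = round(expansion_fraction * n_clonotypes)`).
#' @param total_rearrangements exact total molecule count (depth); singleton
#'   clonotypes fill whatever the expanded clones do not consume, so the sum
#'   of counts always equals this value.
#' @param expansion_fraction proportion of the clonotype budget drawn as
#'   expanded clones, in `[0, 1]`.
#' @param expansion_shape geometric parameter `q` of the expanded-clone size
#'   law `P(S = k) = q(1-q)^(k-2)`, `k >= 2`; mean size `1 + 1/q`.
#' @param seed integer seed.
#' @return list of class `repertoire_spec`.
#' @export
repertoire_spec <- function(n_clonotypes, total_rearrangements,
                            expansion_fraction = 0, expansion_shape = 0.2,
                            seed = NULL) {
  if (n_clonotypes < 1L || total_rearrangements < 1L)
    stop("n_clonotypes and total_rearrangements must be positive")
  if (n_clonotypes > total_rearrangements)
    stop("infeasible spec: n_clonotypes > total_rearrangements")
  if (expansion_fraction < 0 || expansion_fraction > 1)
    stop("expansion_fraction must be in [0, 1]")
  if (expansion_shape <= 0 || expansion_shape > 1)
    stop("expansion_shape must be in (0, 1]")
  structure(list(n_clonotypes = as.integer(n_clonotypes),
                 total_rearrangements = as.integer(total_rearrangements),
                 expansion_fraction = expansion_fraction,
                 expansion_shape = expansion_shape, seed = seed),
            class = "repertoire_spec")
}

# draw the clone-size multiset for a spec (expanded sizes first, then 1s)
draw_clone_sizes <- function(spec) {
  n_exp <- round(spec$expansion_fraction * spec$n_clonotypes)
  total <- spec$total_rearrangements
  if (n_exp == 0L) return(rep.int(1L, total))
  sizes <- 2L + stats::rgeom(n_exp, prob = spec$expansion_shape)
  # truncate to the molecule budget, preserving earlier draws
  remaining <- total
  for (k in seq_len(n_exp)) {
    cap <- remaining - 2L * (n_exp - k)
    sizes[k] <- max(2L, min(sizes[k], cap))
    remaining <- remaining - sizes[k]
  }
  c(sizes, rep.int(1L, max(0L, remaining)))
}

#' Simulate one repertoire
#'
#' Draws clone sizes under `spec` (exact total, expanded clones
#' heavy-tailed, remainder singletons). With a germline reference the
#' clonotypes are realised as distinct productive V(D)J recombinations with
#' assembled sequences, ready for read simulation; without one, only the
#' count structure is produced (the fast path for cohort-scale diversity
#' studies).
#'
#' @param spec a [repertoire_spec()].
#' @param segments optional [make_germline_reference()]; when supplied,
#'   sequences are generated.
#' @param chain TCR chain when sequences are generated.
#' @param sample_id sample identifier.
#' @return list of class `sim_repertoire`: `counts` (a
#'   [clonotype_vector()]), and when sequences were generated a `table`
#'   tibble (`v_call`, `d_call`, `j_call`, `junction`, `productive`,
#'   `duplicate_count`, `sequence`).
#' @export
simulate_repertoire <- function(spec, segments = NULL, chain = "beta",
                                sample_id = "sample") {
  stopifnot(inherits(spec, "repertoire_spec"))
  with_seed(spec$seed, {
    sizes <- draw_clone_sizes(spec)
    tab <- NULL
    if (!is.null(segments)) {
      n <- length(sizes)
      seen <- character(0)
      rows <- vector("list", n)
      for (i in seq_len(n)) {
        for (try in seq_len(1000L)) {
          rc <- simulate_recombination(segments, chain)
          key <- paste(rc$v_name, rc$cdr3_nt, rc$j_name, sep = "|")
          if (rc$productive && !(key %in% seen)) break
        }
        if (!rc$productive) stop("could not draw a productive clonotype")
        seen <- c(seen, key)
        rows[[i]] <- rc
      }
      tab <- tibble::tibble(
        v_call = vapply(rows, `[[`, character(1), "v_name"),
        d_call = vapply(rows, `[[`, character(1), "d_name"),
        j_call = vapply(rows, `[[`, character(1), "j_name"),
        junction = vapply(rows, `[[`, character(1), "cdr3_nt"),
        productive = TRUE,
        duplicate_count = as.integer(sizes),
        sequence = vapply(rows, `[[`, character(1), "sequence"))
    }
    structure(list(sample_id = sample_id, chain = chain,
                   counts = clonotype_vector(sizes, sample_id),
                   table = tab),
              class = "sim_repertoire")
  })
}

#' Specification of a simulated cohort
#'
#' Groups share a base expansion fraction; `effect_delta` is added to the
#' expansion fraction of the designated group(s) only, so `effect_delta = 0`
#' yields exchangeable groups (the permutation null) and a large delta a
#' detectable diversity difference. Per-sample depth is drawn log-uniformly
#' over `depth_range`, reproducing rearrangement counts that vary over
#' orders of magnitude among samples.
#'
#' @param groups named numeric vector: group label -> number of samples
#'   (each `>= 2`).
#' @param base_expansion base expansion fraction for all groups.
#' @param effect_delta shift added to `base_expansion` in `effect_groups`.
#' @param effect_groups labels receiving the shift (default: last group).
#' @param depth_range per-sample total-rearrangement range (log-uniform).
#' @param expansion_shape geometric parameter of expanded-clone sizes.
#' @param cell_type,chain annotations carried through to samples.
#' @param seed master integer seed.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(groups, base_expansion = 0.05, effect_delta = 0,
                        effect_groups = NULL, depth_range = c(1e3, 1e5),
                        expansion_shape = 0.2, cell_type = "CD8",
                        chain = "beta", seed = 1L) {
  if (is.null(names(groups)) || any(groups < 2))
    stop("groups must be a named vector with >= 2 samples per group")
  if (is.null(effect_groups)) effect_groups <- names(groups)[length(groups)]
  if (!all(effect_groups %in% names(groups)))
    stop("effect_groups must name groups")
  f_hi <- base_expansion + effect_delta
  if (f_hi < 0 || f_hi > 1) stop("shifted expansion fraction outside [0, 1]")
  structure(list(groups = groups, base_expansion = base_expansion,
                 effect_delta = effect_delta, effect_groups = effect_groups,
                 depth_range = depth_range,
                 expansion_shape = expansion_shape,
                 cell_type = cell_type, chain = chain, seed = seed),
            class = "cohort_spec")
}

#' Simulate a cohort of repertoires
#'
#' Emits one sample per requested slot, labelled `<group>_<i>`, with depth
#' drawn log-uniformly over the spec's range and a clonotype budget sized so
#' the expected clone-size mixture is self-consistent with that depth. Each
#' sample gets a seed derived from the master seed and its id, so the cohort
#' is reproducible sample-by-sample.
#'
#' @param cspec a [cohort_spec()].
#' @param segments optional germline reference; when supplied each sample
#'   also carries a sequence-level truth table (slow; intended for small
#'   cohorts).
#' @return tibble with columns `sample_id`, `group`, `cell_type`, `chain`,
#'   `expansion_fraction`, `depth`, and list-column `repertoire`
#'   (`sim_repertoire` objects).
#' @export
simulate_cohort <- function(cspec, segments = NULL) {
  stopifnot(inherits(cspec, "cohort_spec"))
  rows <- list()
  for (g in names(cspec$groups)) {
    f <- cspec$base_expansion +
      if (g %in% cspec$effect_groups) cspec$effect_delta else 0
    for (i in seq_len(cspec$groups[[g]])) {
      sid <- sprintf("%s_%02d", g, i)
      sseed <- derive_seed(cspec$seed, "sample", sid)
      depth <- with_seed(derive_seed(sseed, "depth"), {
        lr <- log(cspec$depth_range)
        round(exp(stats::runif(1, lr[1], lr[2])))
      })
      # clonotype budget consistent with the expected clone-size mixture
      mean_exp_size <- 1 + 1 / cspec$expansion_shape
      n_clono <- max(1L, round(depth / (1 - f + f * mean_exp_size)))
      spec <- repertoire_spec(n_clonotypes = min(n_clono, depth),
                              total_rearrangements = depth,
                              expansion_fraction = f,
                              expansion_shape = cspec$expansion_shape,
                              seed = sseed)
      rep <- simulate_repertoire(spec, segments, cspec$chain, sid)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        sample_id = sid, group = g, cell_type = cspec$cell_type,
        chain = cspec$chain, expansion_fraction = f, depth = depth,
        repertoire = list(rep))
    }
  }
  dplyr::bind_rows(rows)
}

#' Extract the clonotype-count vectors of a simulated cohort
#'
#' @param cohort a [simulate_cohort()] tibble.
#' @return named list of [clonotype_vector()]s.
#' @export
cohort_counts <- function(cohort) {
  out <- lapply(cohort$repertoire, function(r) r$counts)
  names(out) <- cohort$sample_id
  out
}
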