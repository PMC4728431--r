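#' Run the full discovery workflow end to end
#'
#' Orchestrates the stages in dependency order: personalize the genome with
#' the variant set, build the control (canonical proteome) and all-frames
#' (six-frame sliding-window) databases, optimize the score/affinity
#' thresholds on the control-database identifications at the target FDR,
#' apply them to the all-frames identifications (whose decoy FDR is
#' re-evaluated and reported), split accepted peptides into conventional and
#' putative cryptic MAPs, and run the cryptic filtering/classification
#' cascade. The returned manifest reconciles every putative cryptic peptide
#' into exactly one validated MAP or one discard.
#'
#' @param genome Reference genome (named character vector).
#' @param models Named list of TranscriptModel objects.
#' @param expression Expression data.frame (transcript_id, fpkm).
#' @param variants SNV data.frame (may have zero rows).
#' @param reads Named character vector of reads.
#' @param psms PSM data.frame.
#' @param affinities Affinity data.frame.
#' @param alleles The subject's HLA allele names.
#' @param cfg A [build_config()].
#' @param fdr_target_percent Target FDR for threshold optimization.
#' @param validated Optional named logical for the spectrum-validation step.
#' @return List with `manifest` (parameters and reconciled counts),
#'   `thresholds`, `conventional` (data.frame of conventional MAP records),
#'   `cryptic` (validated cryptic MAP records), `discards`, `loci`,
#'   `control_db` and `allframes_db`.
#' @export
run_pipeline <- function(genome, models, expression, variants, reads, psms,
                         affinities, alleles, cfg = build_config(),
                         fdr_target_percent = 5, validated = NULL) {
  personalized <- apply_variants(genome, variants)
  control_db <- build_control_db(personalized, models)
  allframes_db <- build_allframes_db(reads, cfg)

  thr <- optimize_thresholds(psms[psms$database %in% c("control", "both"), ],
                             affinities, alleles, fdr_target_percent)
  fdr_allframes <- compute_fdr(psms[psms$database %in% c("allframes", "both"), ],
                               affinities, thr$score_min, thr$ic50_max_nM, alleles)
  acc_allframes <- accepted_peptides(psms, affinities, thr$score_min,
                                     thr$ic50_max_nM, alleles,
                                     database = c("allframes", "both"))
  acc_control <- accepted_peptides(psms, affinities, thr$score_min,
                                   thr$ic50_max_nM, alleles,
                                   database = c("control", "both"))
  split <- split_conventional_cryptic(acc_allframes, acc_control)

  ann <- annotate_cryptic(split$putative_cryptic, personalized, models,
                          expression, validated = validated)
  conv <- map_conventional(split$conventional, control_db, personalized,
                           models, expression)
  discard_counts <- if (nrow(ann$discards)) table(ann$discards$reason) else table(character())
  manifest <- list(
    parameters = list(score_min = thr$score_min, ic50_max_nM = thr$ic50_max_nM,
                      fdr_target_percent = fdr_target_percent,
                      window_bp = cfg$window_bp, s_min = cfg$s_min),
    counts = list(
      n_reads = length(reads),
      n_allframes_entries = nrow(allframes_db),
      n_control_proteins = nrow(control_db),
      n_allframes_identified = length(acc_allframes),
      n_conventional = length(split$conventional),
      n_putative_cryptic = length(split$putative_cryptic),
      n_validated_cryptic = nrow(ann$maps),
      n_discarded = nrow(ann$discards),
      n_discarded_by_reason = as.list(discard_counts)),
    fdr = list(control = thr$fdr,
               allframes_at_control_thresholds = fdr_allframes),
    cryptic_fraction_percent =
      if (length(acc_allframes) > 0)
        100 * nrow(ann$maps) / length(acc_allframes) else NA_real_)
  if (manifest$counts$n_putative_cryptic !=
      manifest$counts$n_validated_cryptic + manifest$counts$n_discarded)
    stop("bookkeeping failure: putative cryptic != validated + discarded")
  list(manifest = manifest, thresholds = thr, conventional = conv$maps,
       cryptic = ann$maps, discards = ann$discards,
       loci = c(ann$loci, conv$loci), control_db = control_db,
       allframes_db = allframes_db)
}
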