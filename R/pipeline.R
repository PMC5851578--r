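#' Run the full repeat-discovery pipeline
#'
#' Executes the stages end to end: genome self-alignment, pile construction,
#' single-linkage family clustering, per-family consensus, consensus
#' cleaning (SSR / host-gene filter), classification against the TE
#' reference library, genome annotation with the combined library (kept
#' consensus set plus reference library) at a relaxed identity floor,
#' copy-number analysis and segmental-duplication triage of the unclassified
#' set, repeat-content summary and an active-element scan of the surviving
#' consensus sequences. Deterministic given the seed.
#'
#' @param genome DNAStringSet (e.g. [readGenome()]).
#' @param te_library DNAStringSet reference library (may be empty).
#' @param host_db,rt_db AAStringSet protein databases (may be empty).
#' @param params [AlignerParams-class] for the self-alignment.
#' @param annot_params [AlignerParams-class] for annotation searches.
#' @param filter [FilterParams-class].
#' @param pile_min_overlap see [buildPiles()].
#' @param length_fraction,max_sample see [selectMembers()].
#' @param high_copy_threshold see [triageUnclassified()].
#' @param min_orf_nt,min_rt_aa see [flagPotentiallyActive()].
#' @param seed integer seed for member sampling.
#' @param out_dir when given, all outputs are written there (see
#'   [writePipelineOutputs()]).
#' @param verbose report per-stage progress and counts.
#' @return list with elements alignments, families, consensus (classified
#'   [ConsensusSet-class]), annotation (resolved GRanges), summary,
#'   copy_number, regression (or NULL), triage, active, manifest and the
#'   configuration used.
#' @export
runPipeline <- function(genome, te_library = Biostrings::DNAStringSet(),
                        host_db = Biostrings::AAStringSet(),
                        rt_db = Biostrings::AAStringSet(),
                        params = alignerParams(),
                        annot_params = annotationParams(),
                        filter = filterParams(), pile_min_overlap = 0.5,
                        length_fraction = 0.95, max_sample = 100L,
                        high_copy_threshold = 2000L, min_orf_nt = 1500L,
                        min_rt_aa = 200L, seed = 1L, out_dir = NULL,
                        verbose = FALSE) {
  t0 <- proc.time()[3]
  stage <- function(what, expr) {
    res <- tryCatch(expr, error = function(e)
      stop("stage '", what, "' failed: ", conditionMessage(e), call. = FALSE))
    .msg(verbose, sprintf("[%s] done (%.1f s)", what, proc.time()[3] - t0))
    res
  }
  aln <- stage("align", selfAlign(genome, params, verbose = verbose))
  inst <- stage("piles", buildPiles(alignmentImages(aln), pile_min_overlap))
  fams <- stage("cluster", linkFamilies(inst, aln))
  cons <- stage("consensus",
                buildConsensusSet(fams, genome, length_fraction, max_sample,
                                  rng_seed = seed, verbose = verbose))
  cons <- stage("filter", filterConsensusSet(cons, host_db, rt_db, filter))
  kept <- keptConsensus(cons)
  kept <- stage("classify", classifyConsensus(kept, te_library, filter,
                                              annot_params))
  # push classification back into the full set
  info <- consensusInfo(cons)
  ki <- consensusInfo(kept)
  m <- match(ki$family_id, info$family_id)
  for (cl in setdiff(colnames(ki), colnames(info)))
    info[[cl]] <- NA_character_
  for (cl in colnames(ki)) info[[cl]][m] <- ki[[cl]]
  cons <- initialize(cons, info = info)

  combined <- c(consensusSequences(kept), te_library)
  cls <- S4Vectors::metadata(te_library)$class
  cons_cls <- ifelse(ki$class == "well_annotated", ki$ref_class, "unclassified")
  S4Vectors::metadata(combined)$class <- c(
    stats::setNames(cons_cls, ki$family_id),
    if (is.null(cls) && length(te_library))
      stats::setNames(rep("Unknown", length(te_library)), names(te_library))
    else cls)
  annotation <- if (length(combined))
    stage("annotate", annotateGenome(genome, combined, annot_params))
  else GRanges()
  summary_tab <- stage("summary",
    summarizeRepeatContent(annotation, sum(Biostrings::width(genome))))

  uncls <- unclassifiedConsensus(kept)
  cn <- stage("copy_number", copyNumberTable(annotation, uncls))
  reg <- tryCatch(loglogRegression(cn), error = function(e) NULL)
  triage <- stage("triage", triageUnclassified(cn, annotation,
                                               high_copy_threshold))
  active <- if (length(rt_db) && length(kept))
    stage("active_scan",
          flagPotentiallyActive(consensusSequences(kept), rt_db,
                                min_orf_nt, min_rt_aa))
  else NULL

  manifest <- .buildManifest(cons, fams)
  config <- list(params = params, annot_params = annot_params,
                 filter = filter, pile_min_overlap = pile_min_overlap,
                 length_fraction = length_fraction, max_sample = max_sample,
                 high_copy_threshold = high_copy_threshold,
                 min_orf_nt = min_orf_nt, min_rt_aa = min_rt_aa, seed = seed)
  res <- list(alignments = aln, families = fams, consensus = cons,
              annotation = annotation, summary = summary_tab,
              copy_number = cn, regression = reg, triage = triage,
              active = active, manifest = manifest, config = config)
  if (!is.null(out_dir)) writePipelineOutputs(res, genome, out_dir)
  res
}

# audit trail: every consensus -> sampled member instances -> genome intervals
.buildManifest <- function(cons, fams) {
  inst <- instanceRanges(fams)
  iid <- mcols(inst)$instance_id
  rows <- lapply(seq_along(cons), function(i) {
    sel <- sampledMembers(cons)[[i]]
    m <- match(sel, iid)
    data.frame(family_id = consensusInfo(cons)$family_id[i],
               instance_id = sel,
               seqnames = as.character(seqnames(inst))[m],
               start = start(inst)[m], end = end(inst)[m],
               strand = as.character(strand(inst))[m],
               stringsAsFactors = FALSE)
  })
  if (length(rows)) do.call(rbind, rows)
  else data.frame(family_id = character(), instance_id = character(),
                  seqnames = character(), start = integer(), end = integer(),
                  strand = character(), stringsAsFactors = FALSE)
}

#' Write all pipeline outputs to a directory
#'
#' Writes the alignment table, family GFF3 and per-family member FASTA, the
#' audit-trail edge list and manifest, the consensus library FASTA, the
#' classification table, the resolved genome annotation (GFF3 + TSV), the
#' repeat-content summary, the copy-number table with the regression report,
#' coverage profiles of reviewed high-copy consensuses and the active-scan
#' table.
#'
#' @param res result of [runPipeline()].
#' @param genome the genome the pipeline ran on.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
writePipelineOutputs <- function(res, genome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(dir, ...)
  writeAlignmentsTsv(res$alignments, fp("alignments.tsv"))
  writeFamilyGff(res$families, fp("families.gff3"))
  fam_dir <- fp("families")
  dir.create(fam_dir, showWarnings = FALSE)
  for (fid in familyIds(res$families))
    Biostrings::writeXStringSet(
      exportFamilyMembers(res$families, genome, fid),
      file.path(fam_dir, paste0(fid, ".fa")))
  utils::write.table(as.data.frame(familyEdges(res$families)),
                     fp("family_edges.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  keep <- !consensusInfo(res$consensus)$removed
  Biostrings::writeXStringSet(consensusSequences(res$consensus)[keep],
                              fp("consensus.fa"))
  utils::write.table(as.data.frame(consensusInfo(res$consensus)),
                     fp("classification.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (length(res$annotation)) {
    ann <- res$annotation
    mcols(ann) <- DataFrame(type = "repeat_region",
                            ID = sprintf("hit%06d", seq_along(ann)),
                            Name = mcols(ann)$query_id,
                            class = mcols(ann)$ref_class,
                            identity = round(mcols(ann)$identity, 4))
    writeGff3(ann, fp("annotation.gff3"))
    utils::write.table(as.data.frame(res$annotation), fp("annotation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(res$summary, fp("repeat_content.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(res$copy_number, fp("copy_number.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(res$regression)) {
    r <- res$regression
    reg_tab <- data.frame(
      term = c("intercept", "log10_length"),
      estimate = c(r$intercept, r$slope),
      std_error = c(r$intercept_se, r$slope_se),
      t_value = r$t_value, p_value = r$p_value)
    utils::write.table(reg_tab, fp("regression.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  for (pid in names(res$triage$profiles)) {
    pr <- res$triage$profiles[[pid]]
    utils::write.table(
      data.frame(position = seq_along(pr$depth), depth = pr$depth),
      fp(paste0("coverage_", pid, ".tsv")), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  if (!is.null(res$active))
    utils::write.table(res$active, fp("active_scan.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  utils::write.table(res$manifest, fp("manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
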