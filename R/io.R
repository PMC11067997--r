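# Readers, writers and the pipeline driver.
#
# File conventions: TSV with header rows for tables; FASTA (80-column) for
# sequences; BED-like three-column span files with 0-based half-open
# coordinates for region annotations; JSON for reports.

#' Read an aligned FASTA into a CodingAlignment
#'
#' @param path FASTA file of aligned (gapped) coding sequences.
#' @param regions Optional named [IRanges::IRanges] or path to a BED-like
#'   span file (see [readRegionsBed()]).
#' @return A validated [CodingAlignment-class].
#' @export
readFastaAlignment <- function(path, regions = IRanges::IRanges()) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) < 2L) stop("need at least 2 records in ", path)
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence id in ", path, ": ",
         names(seqs)[anyDuplicated(names(seqs))])
  if (is.character(regions)) regions <- readRegionsBed(regions)
  validateAlignment(seqs, regions = regions)
}

#' Read a BED-like region annotation file
#'
#' Three tab-separated columns (name, start, end) with 0-based half-open
#' coordinates; comment lines start with '#'.
#'
#' @param path Path to the span file.
#' @return Named [IRanges::IRanges] in 1-based closed coordinates.
#' @export
readRegionsBed <- function(path) {
  df <- read.delim(path, header = FALSE, comment.char = "#",
                   col.names = c("name", "start", "end"))
  IRanges::IRanges(start = df$start + 1L, end = df$end,
                   names = as.character(df$name))
}

#' Write haplotypes as FASTA (with an HVR sidecar)
#'
#' Writes the nucleotide sequences with allele ids as headers, plus a
#' BED-like sidecar (`<path>.hvr.tsv`) holding each haplotype's HVR span
#' in 0-based half-open codon coordinates so the set round-trips.
#'
#' @param haps A [HaplotypeSet-class].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
writeHaplotypeFasta <- function(haps, path) {
  stopifnot(is(haps, "HaplotypeSet"))
  Biostrings::writeXStringSet(haps@dna, path, width = 80L)
  side <- data.frame(allele = names(haps@dna),
                     hvr_start = IRanges::start(haps@hvr) - 1L,
                     hvr_end = IRanges::end(haps@hvr))
  write.table(side, paste0(path, ".hvr.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read haplotypes written by [writeHaplotypeFasta()]
#'
#' @param path FASTA path (expects the `<path>.hvr.tsv` sidecar).
#' @return A [HaplotypeSet-class].
#' @export
readHaplotypeFasta <- function(path) {
  dna <- Biostrings::readDNAStringSet(path)
  side <- read.delim(paste0(path, ".hvr.tsv"))
  side <- side[match(names(dna), side$allele), ]
  HaplotypeSet(dna, IRanges::IRanges(side$hvr_start + 1L, side$hvr_end))
}

.readTsv <- function(path, required) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("missing column(s) in ", path, ": ",
         paste(missing, collapse = ", "))
  df
}

#' Read a genotype table
#'
#' Tab-separated with header: individual, population, g1 (logical),
#' allele1, allele2 (empty/NA for hemizygotes).
#'
#' @param path TSV path.
#' @return data.frame with validated columns and an `nAlleles` column.
#' @export
readGenotypeTable <- function(path) {
  df <- .readTsv(path, c("individual", "population", "allele1"))
  if (!"allele2" %in% names(df)) df$allele2 <- NA_character_
  if (!"g1" %in% names(df)) df$g1 <- FALSE
  df$allele2[df$allele2 %in% c("", ".")] <- NA_character_
  df$nAlleles <- ifelse(is.na(df$allele2), 1L, 2L)
  bad <- which(!is.na(df$allele2) & df$allele1 == df$allele2)
  if (length(bad))
    stop("row ", bad[1L], ": homozygous genotype in an adult table")
  df
}

#' Read a brood outcome table
#'
#' Tab-separated with header: mother_karyotype, mother_allele,
#' father_allele1, father_allele2, and the outcome counts hatched,
#' black_egg, white_egg, collapsed.
#'
#' @param path TSV path.
#' @return data.frame of validated brood rows.
#' @export
readBroodTable <- function(path) {
  df <- .readTsv(path, c("mother_karyotype", "mother_allele",
                         "father_allele1", "father_allele2",
                         "hatched", "black_egg", "white_egg", "collapsed"))
  cnt <- df[, c("hatched", "black_egg", "white_egg", "collapsed")]
  bad <- which(apply(cnt, 1L, function(r) any(r < 0)))
  if (length(bad)) stop("row ", bad[1L], ": negative egg count")
  df
}

#' Read an expression matrix with class sidecars
#'
#' Reads a gene x sample abundance TSV (first column gene id) together
#' with two sidecar TSVs assigning each gene to a chromosome class (A/Z)
#' and each sample to a zygosity class (hem/het/hom).
#'
#' @param matrixPath Abundance TSV.
#' @param geneClassPath TSV with columns gene, class.
#' @param sampleClassPath TSV with columns sample, class.
#' @return A [SummarizedExperiment::SummarizedExperiment] (assay "tpm").
#' @export
readExpressionTable <- function(matrixPath, geneClassPath,
                                sampleClassPath) {
  df <- read.delim(matrixPath, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  if (any(m < 0)) {
    bad <- which(rowSums(m < 0) > 0)[1L]
    stop("row ", bad, " ('", rownames(m)[bad], "'): negative abundance")
  }
  gc <- .readTsv(geneClassPath, c("gene", "class"))
  sc <- .readTsv(sampleClassPath, c("sample", "class"))
  if (!all(rownames(m) %in% gc$gene)) stop("gene without a class label")
  if (!all(colnames(m) %in% sc$sample)) stop("sample without a class label")
  if (!all(sc$class %in% c("hem", "het", "hom")))
    stop("unknown sample class label")
  if (!all(gc$class %in% c("A", "Z"))) stop("unknown gene class label")
  SummarizedExperiment::SummarizedExperiment(
    assays = list(tpm = m),
    rowData = S4Vectors::DataFrame(
      geneClass = gc$class[match(rownames(m), gc$gene)]),
    colData = S4Vectors::DataFrame(
      zygosity = sc$class[match(colnames(m), sc$sample)],
      row.names = colnames(m)))
}

#' Write an expression SummarizedExperiment as TSV + sidecars
#'
#' @param se A SummarizedExperiment with `geneClass` and `zygosity`.
#' @param matrixPath,geneClassPath,sampleClassPath Output paths.
#' @return `matrixPath`, invisibly.
#' @export
writeExpressionTable <- function(se, matrixPath, geneClassPath,
                                 sampleClassPath) {
  .checkExprSE(se)
  m <- SummarizedExperiment::assay(se)
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  write.table(df, matrixPath, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(gene = rownames(m),
                         class = SummarizedExperiment::rowData(se)$geneClass),
              geneClassPath, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample = colnames(m),
                         class = SummarizedExperiment::colData(se)$zygosity),
              sampleClassPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(matrixPath)
}

## ---- pipeline ------------------------------------------------------------

#' Run the simulation-to-analysis pipeline
#'
#' Executes the requested stages in dependency order on simulated data:
#' `simulate` (forward simulation; writes haplotype FASTA and population
#' TSVs), `diversity` (sliding-window and HVR statistics on the aligned
#' simulated haplotypes), `richness` (spectrum and iChao1 on the sampled
#' female alleles), `compat` (resampling null over the simulated male
#' genotypes), and `dosage` (Z:A analysis of a simulated expression
#' matrix).  Identical config and seed give an identical report.
#'
#' @param config A [SimConfig-class] driving the simulation stage.
#' @param stages Character vector of stages to run (default all).
#' @param outDir Output directory (created if missing); `NULL` suppresses
#'   file output.
#' @return Named list report (one element per executed stage); also
#'   written to `<outDir>/report.json` when `outDir` is given.
#' @export
runPipeline <- function(config = SimConfig(),
                        stages = c("simulate", "diversity", "richness",
                                   "compat", "dosage"),
                        outDir = NULL) {
  known <- c("simulate", "diversity", "richness", "compat", "dosage")
  if (!length(stages)) {
    warning("empty stage list: nothing to do")
    return(invisible(list()))
  }
  if (!all(stages %in% known))
    stop("unknown stage: ", paste(setdiff(stages, known), collapse = ", "))
  stages <- known[known %in% stages]   # dependency order
  if (!is.null(outDir) && !dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)
  report <- list(seed = config@seed)
  msg <- function(stage, ...) {
    message(sprintf("stage=%s %s", stage,
                    paste(sprintf("%s=%s", names(list(...)),
                                  unlist(list(...))), collapse = " ")))
  }

  state <- NULL
  if ("simulate" %in% stages ||
      any(c("diversity", "richness", "compat") %in% stages)) {
    t0 <- proc.time()[["elapsed"]]
    state <- simulatePopulation(config)
    msg("simulate", extinct = isExtinct(state),
        seconds = round(proc.time()[["elapsed"]] - t0, 2))
    if (isExtinct(state)) {
      report$simulate <- list(extinct = TRUE,
                              generation = state@extinctGeneration)
      if (!is.null(outDir))
        jsonlite::write_json(report, file.path(outDir, "report.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
      return(report)
    }
    traj <- alleleTrajectory(state)
    report$simulate <- list(
      extinct = FALSE,
      nAllelesFinal = length(traj[[length(traj)]]),
      nFemales = nrow(simFemales(state)),
      nMales = nrow(simMales(state)))
    if (!is.null(outDir) && "simulate" %in% stages) {
      writeHaplotypeFasta(simHaplotypes(state),
                          file.path(outDir, "haplotypes.fasta"))
      write.table(simFemales(state), file.path(outDir, "females.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(simMales(state), file.path(outDir, "males.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  if ("diversity" %in% stages) {
    aln <- alignHaplotypes(simHaplotypes(state))
    win <- slidingWindowDiversity(aln, bootReps = 0L)
    hl <- hvrLengthDistribution(simHaplotypes(state))
    report$diversity <- list(
      nWindows = nrow(win),
      maxPiSyn = max(win$piSyn, na.rm = TRUE),
      maxPiNonsyn = max(win$piNonsyn, na.rm = TRUE),
      hvrLenMin = hl$min, hvrLenMax = hl$max)
    if (!is.null(outDir))
      write.table(win, file.path(outDir, "windows.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    msg("diversity", windows = nrow(win))
  }

  if ("richness" %in% stages) {
    counts <- AlleleCounts(simFemales(state)$allele)
    spec <- frequencySpectrum(counts)
    est <- iChao1(spec)
    report$richness <- list(
      sObs = spec$sObs, n = spec$n,
      singletonProportion = spec$singletonProportion,
      chao1 = est$chao1, ichao1 = est$ichao1,
      ciLow = est$ciLow, ciHigh = est$ciHigh)
    msg("richness", sObs = spec$sObs)
  }

  if ("compat" %in% stages) {
    males <- simMales(state)
    counts <- AlleleCounts(c(males$allele1, males$allele2))
    obs <- genotypePairDistances(as.matrix(males), simHaplotypes(state))
    simPairs <- simulateHeterozygousMales(counts,
                                          nMales = max(1000L, nrow(males)))
    simd <- genotypePairDistances(simPairs, simHaplotypes(state))
    cmp <- compareDistanceDistributions(obs, simd)
    report$compat <- list(
      nObserved = nrow(obs), nSimulated = nrow(simd),
      ksHvrEdit = cmp$hvrEdit$ks, pHvrEdit = cmp$hvrEdit$p)
    msg("compat", males = nrow(obs))
  }

  if ("dosage" %in% stages) {
    se <- simulateExpressionMatrix(2000L, 200L, seed = config@seed)
    sef <- filterExpression(se)
    za <- zaMedians(sef)
    rel <- pairwiseRelativeExpression(sef, "hom", "hem")
    report$dosage <- list(
      zaRatio = as.list(za$zaRatio),
      homHemMedianZ = rel$medianZ, homHemMedianA = rel$medianA)
    if (!is.null(outDir))
      writeExpressionTable(se, file.path(outDir, "expression.tsv"),
                           file.path(outDir, "gene_classes.tsv"),
                           file.path(outDir, "sample_classes.tsv"))
    msg("dosage", medianZ = round(rel$medianZ, 3))
  }

  if (!is.null(outDir))
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report
}
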