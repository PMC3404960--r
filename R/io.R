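# File formats: FASTA reads (with the <line>|<locus>|<idx> id
# convention), genotype/phenotype tables, map and candidate tables,
# truth JSON, and the validated run configuration.

#' Read library reads from FASTA
#'
#' Wraps [Biostrings::readDNAStringSet()] with the checks the pipeline
#' relies on: duplicate identifiers and non-IUPAC characters are
#' explicit errors. Line labels are parsed from the `<line>|...` id
#' convention when present and attached as the `"lines"` attribute
#' (`NA` for ids without a prefix).
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
readFastaReads <- function(path) {
  x <- tryCatch(Biostrings::readDNAStringSet(path),
                error = function(e)
                  stop("FASTA parse error in '", path, "': ",
                       conditionMessage(e), call. = FALSE))
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids))
    stop("duplicate FASTA id: '", ids[duplicated(ids)][1L], "'")
  out <- as.character(x)
  names(out) <- ids
  attr(out, "lines") <- .lineOf(ids)
  out
}

#' Write reads to FASTA
#'
#' Sequences are wrapped at 60 columns; a write/read round trip is the
#' identity on ids and sequences.
#'
#' @param reads named character vector or [Biostrings::DNAStringSet].
#' @param path output file.
#' @export
writeFastaReads <- function(reads, path) {
  if (!methods::is(reads, "DNAStringSet"))
    reads <- Biostrings::DNAStringSet(reads)
  Biostrings::writeXStringSet(reads, path, width = 60L)
  invisible(path)
}

.sepFor <- function(path) if (grepl("\\.csv$", path)) "," else "\t"

#' Read an F2 genotype matrix
#'
#' CSV or TSV (by extension) with a header row; the first column holds
#' individual ids, remaining columns are loci with single-character
#' genotype codes. An illegal code is reported with its row and column.
#'
#' @param path input file.
#' @return a [GenotypeMatrix-class].
#' @export
readGenotypes <- function(path) {
  d <- read.table(path, sep = .sepFor(path), header = TRUE,
                  colClasses = "character", check.names = FALSE)
  if (ncol(d) < 2L) stop("genotype table needs an id column plus loci")
  m <- as.matrix(d[, -1L, drop = FALSE])
  rownames(m) <- d[[1L]]
  bad <- which(!(m %in% GENO_CODES))
  if (length(bad)) {
    r <- ((bad[1L] - 1L) %% nrow(m)) + 1L
    cc <- ((bad[1L] - 1L) %/% nrow(m)) + 1L
    stop(sprintf("illegal genotype code '%s' at row %d ('%s'), column '%s'",
                 m[bad[1L]], r, rownames(m)[r], colnames(m)[cc]))
  }
  GenotypeMatrix(m)
}

#' @rdname readGenotypes
#' @param geno a [GenotypeMatrix-class].
#' @export
writeGenotypes <- function(geno, path) {
  m <- genoCodes(geno)
  d <- data.frame(id = rownames(m), m, check.names = FALSE)
  write.table(d, path, sep = .sepFor(path), quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a phenotype table
#'
#' CSV/TSV with a header: an `id` column (or first column treated as
#' ids) and one numeric column per trait.
#'
#' @param path input file.
#' @return data.frame with `id` first and numeric trait columns.
#' @export
readPhenotypes <- function(path) {
  d <- read.table(path, sep = .sepFor(path), header = TRUE,
                  check.names = FALSE)
  if (!("id" %in% names(d))) names(d)[1L] <- "id"
  d$id <- as.character(d$id)
  for (cn in setdiff(names(d), "id")) {
    v <- suppressWarnings(as.numeric(d[[cn]]))
    if (any(is.na(v) & !is.na(d[[cn]]) & d[[cn]] != "NA"))
      stop("non-numeric phenotype value in column '", cn, "'")
    d[[cn]] <- v
  }
  d[, c("id", setdiff(names(d), "id")), drop = FALSE]
}

#' @rdname readPhenotypes
#' @param phenotypes data.frame with `id` and trait columns.
#' @export
writePhenotypes <- function(phenotypes, path) {
  write.table(phenotypes, path, sep = .sepFor(path), quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write / read a linkage map table
#'
#' TSV with columns `group`, `locus`, `position_cM`, `chi2`, `p`,
#' `df`, `distorted`.
#'
#' @param map a [LinkageMap-class].
#' @param path output file.
#' @export
writeMap <- function(map, path) {
  write.table(mapTable(map), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname writeMap
#' @export
readMap <- function(path) {
  d <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  new("LinkageMap", loci = d)
}

#' Write marker candidates with their primer pairs
#'
#' TSV of the candidate table from [screenClusters()], optionally
#' joined with the best primer pair per candidate.
#'
#' @param candidates candidate data.frame.
#' @param path output file.
#' @param primers optional named list: candidate id -> primer-pair
#'   data.frame from [designPrimers()] (best row used).
#' @export
writeCandidates <- function(candidates, path, primers = NULL) {
  d <- candidates
  if (!is.null(primers)) {
    pick <- function(id, col) {
      p <- primers[[id]]
      if (is.null(p) || !nrow(p)) return(NA)
      p[[col]][1L]
    }
    d$primer_left <- vapply(d$id, function(i)
      as.character(pick(i, "left_seq")), character(1))
    d$primer_right <- vapply(d$id, function(i)
      as.character(pick(i, "right_seq")), character(1))
    d$product_len <- vapply(d$id, function(i)
      as.numeric(pick(i, "product_len")), numeric(1))
  }
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read simulation truth as JSON
#'
#' @param truth a [SimTruth-class].
#' @param path output file.
#' @export
writeTruth <- function(truth, path) {
  jsonlite::write_json(list(lines = truth@lines,
                            teConsensus = truth@teConsensus,
                            ssr = truth@ssr, te = truth@te),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeTruth
#' @export
readTruth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("SimTruth",
      ssr = as.data.frame(x$ssr), te = as.data.frame(x$te),
      teConsensus = if (is.null(x$teConsensus)) "" else x$teConsensus,
      lines = x$lines)
}

#' Default run configuration
#'
#' One validated document holding every module's tunable defaults. Use
#' [readRunConfig()] to merge a YAML file over the defaults; unknown
#' keys are rejected.
#'
#' @return nested named list of defaults.
#' @export
defaultRunConfig <- function() {
  list(
    seed = 1L,
    ssrscan = list(min_repeats = list(`2` = 6L, `3` = 5L, `4` = 5L)),
    cluster = list(min_identity = 0.95, k = 15L, min_shared_keys = 3L,
                   min_aligned_cols = 40L),
    screen = list(min_reads_per_line = 1L,
                  te_min_len = 30L, te_min_identity = 0.80),
    primers = list(len_range = c(18L, 27L), tm_range = c(57, 63),
                   gc_range = c(0.30, 0.70), product_range = c(80L, 400L),
                   max_homopolymer = 4L, max_3p_comp = 4L,
                   opt_len = 20L, opt_tm = 60, opt_gc = 0.5),
    linkmap = list(lod_threshold = 4, max_rf = 0.30,
                   distortion_alpha = 0.05),
    qtl = list(step_cM = 1, n_perm = 1000L, alpha = 0.05),
    gmm = list(max_combo = 2L, min_samples = 1L),
    simulate = list(n_ssr_loci = 200L, frac_polymorphic = 0.3,
                    repeat_count_range = c(8L, 16L), flank_len = 150L,
                    n_te_sites = 100L, frac_te_line_specific = 0.43,
                    read_error_rate = 0.005, reads_per_locus_per_line = 4L)
  )
}

.mergeConfig <- function(base, extra, path = "") {
  for (k in names(extra)) {
    if (!(k %in% names(base)))
      stop("unknown configuration key: ", paste0(path, k))
    if (is.list(base[[k]]) && is.list(extra[[k]]))
      base[[k]] <- .mergeConfig(base[[k]], extra[[k]],
                                paste0(path, k, "."))
    else base[[k]] <- extra[[k]]
  }
  base
}

#' @rdname defaultRunConfig
#' @param path YAML file of overrides.
#' @export
readRunConfig <- function(path) {
  overrides <- yaml::read_yaml(path)
  .mergeConfig(defaultRunConfig(), overrides)
}
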