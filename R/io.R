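# Format boundary. Everything on disk uses the field's standard formats
# (FASTA, VCF 4.x, bedGraph, BED, GFF3, tab-separated tables); everything in
# memory uses 1-based inclusive coordinates. Parsing of the standard formats
# is delegated to Biostrings, rtracklayer and vcfR; this file adds the
# convention conversions and the validation the pipeline relies on.

#' Read a FASTA file
#'
#' @param path path to a FASTA file
#' @return named character vector of sequences; case is preserved (codon-level
#'   routines upper-case internally)
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA in ", path, ": ",
                                           conditionMessage(e)))
  out <- as.character(set)
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector
#' @param path output path
#' @param width line width
#' @return `path`, invisibly
#' @export
write_fasta <- function(seqs, path, width = 70) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a bedGraph coverage track
#'
#' bedGraph lines are 0-based half-open; they are converted to the package's
#' 1-based inclusive intervals with depths unchanged. Adjacent equal-depth
#' lines are preserved as given (no auto-merge). Overlapping lines on one
#' chromosome are an input error, since a coverage track must partition the
#' positions it covers.
#'
#' @param path path to a bedGraph file
#' @return data.frame with columns `chrom`, `start`, `end`, `depth`, sorted by
#'   (chrom, start)
#' @export
read_bedgraph <- function(path) {
  stopifnot(file.exists(path))
  if (file.size(path) == 0 ||
      !any(nzchar(trimws(readLines(path, warn = FALSE)))))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), depth = numeric()))
  gr <- rtracklayer::import(path, format = "bedGraph")
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr),
                    end = GenomicRanges::end(gr),
                    depth = as.numeric(gr$score),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  if (any(out$depth < 0)) stop("negative depth in ", path)
  for (ch in unique(out$chrom)) {
    sub <- out[out$chrom == ch, ]
    if (nrow(sub) > 1 && any(sub$start[-1] <= sub$end[-nrow(sub)]))
      stop("overlapping bedGraph intervals on ", ch, " in ", path)
  }
  out
}

#' Write a coverage track as bedGraph
#'
#' @param track data.frame with `chrom`, `start`, `end`, `depth` (1-based
#'   inclusive; converted to 0-based half-open on output)
#' @param path output path
#' @return `path`, invisibly
#' @export
write_bedgraph <- function(track, path) {
  validate_gi(track)
  df <- data.frame(track$chrom, format(track$start - 1, scientific = FALSE, trim = TRUE),
                   format(track$end, scientific = FALSE, trim = TRUE), track$depth)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write intervals as BED
#'
#' Converts the package's 1-based inclusive intervals to BED's 0-based
#' half-open convention, so `Chr14:39979216-52678755` becomes the line
#' `Chr14<TAB>39979215<TAB>52678755`.
#'
#' @param regions interval table from [gi()]; an optional `name` column is
#'   written as the 4th BED field
#' @param path output path
#' @return `path`, invisibly
#' @export
write_bed <- function(regions, path) {
  validate_gi(regions)
  start0 <- regions$start - 1
  if (any(regions$end <= start0)) stop("invalid BED span (end <= start)")
  df <- data.frame(regions$chrom,
                   format(start0, scientific = FALSE, trim = TRUE),
                   format(regions$end, scientific = FALSE, trim = TRUE))
  if (!is.null(regions$name)) df[[4]] <- regions$name
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file as 1-based inclusive intervals
#'
#' @param path path to a BED file
#' @return interval table (with `name` column if the file has >= 4 fields)
#' @export
read_bed <- function(path) {
  stopifnot(file.exists(path))
  if (file.size(path) == 0)
    return(data.frame(chrom = character(), start = numeric(), end = numeric()))
  gr <- rtracklayer::import(path, format = "bed")
  out <- gr_to_gi(gr)
  nm <- gr$name
  if (!is.null(nm) && !all(is.na(nm))) out$name <- nm
  out
}

#' Read gene features from a GFF3 file
#'
#' @param path path to a GFF3 file
#' @param feature feature type to keep (default `"gene"`)
#' @return interval table with a `gene_id` column
#' @export
read_gff_genes <- function(path, feature = "gene") {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == feature]
  out <- gr_to_gi(gr)
  out$gene_id <- if (!is.null(gr$ID)) as.character(gr$ID) else
    paste0("gene", seq_len(nrow(out)))
  out
}

#' Read a tabular pairwise-hit file (12-column BLAST-style format)
#'
#' Columns: query, subject, percent identity, alignment length, mismatches,
#' gap opens, qstart, qend, sstart, send, evalue, bitscore.
#'
#' @param path path to the hits file
#' @return data.frame with columns `query`, `subject`, `identity`,
#'   `matching_bp` plus query/subject coordinates, in input order
#' @export
read_hits <- function(path) {
  stopifnot(file.exists(path))
  empty <- data.frame(query = character(), subject = character(),
                      identity = numeric(), matching_bp = numeric(),
                      qstart = numeric(), qend = numeric(),
                      sstart = numeric(), send = numeric())
  if (file.size(path) == 0) return(empty)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (!length(lines)) return(empty)
  tab <- utils::read.table(text = lines, sep = "\t",
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 12) stop("expected 12 tab-separated columns in ", path)
  ident <- suppressWarnings(as.numeric(tab[[3]]))
  if (anyNA(ident)) stop("non-numeric identity at line ",
                         which(is.na(ident))[1], " of ", path)
  len <- suppressWarnings(as.numeric(tab[[4]]))
  if (anyNA(len) || any(len < 1)) stop("invalid alignment length in ", path)
  if (any(ident < 0 | ident > 100)) stop("identity outside [0,100] in ", path)
  data.frame(query = tab[[1]], subject = tab[[2]], identity = ident,
             matching_bp = len,
             qstart = as.numeric(tab[[7]]), qend = as.numeric(tab[[8]]),
             sstart = as.numeric(tab[[9]]), send = as.numeric(tab[[10]]),
             stringsAsFactors = FALSE)
}

#' Read a VCF into a genotype matrix
#'
#' Dosage is the count of alt alleles in the GT field; `./.` becomes `NA`.
#' Multi-allelic records are split into one bi-allelic record per alt allele.
#' Site DP is taken from the INFO field (if present) and site quality from the
#' QUAL column.
#'
#' @param path path to a VCF 4.x file (plain text or gzip)
#' @param sample_labels optional data.frame with columns `id`, `sex`,
#'   `subgroup`; every labelled sample must be present in the VCF
#' @return a [geno_matrix()]
#' @export
read_vcf <- function(path, sample_labels = NULL) {
  stopifnot(file.exists(path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix_mat <- v@fix
  if (is.null(dim(fix_mat)))
    fix_mat <- matrix(fix_mat, nrow = 1,
                      dimnames = list(NULL, names(fix_mat)))
  fix <- as.data.frame(fix_mat, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) stop("VCF has no GT field: ", path)
  vcf_samples <- colnames(gt)
  if (!is.null(sample_labels)) {
    missing <- setdiff(sample_labels$id, vcf_samples)
    if (length(missing))
      stop("labelled sample(s) absent from VCF: ",
           paste(missing, collapse = ", "))
  }
  info_dp <- suppressWarnings(as.numeric(sub(".*DP=([0-9.]+).*", "\\1",
                                             vcfR::getINFO(v))))
  qual <- suppressWarnings(as.numeric(fix$QUAL))

  rec_geno <- list(); rec_sites <- list(); k <- 0L
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    gts <- gt[i, ]
    alleles <- strsplit(gts, "[/|]")
    for (ai in seq_along(alts)) {
      if (alts[ai] == fix$REF[i]) next
      dos <- vapply(alleles, function(a) {
        if (length(a) == 0 || anyNA(a) || any(a == "."))
          return(NA_integer_)
        sum(a == as.character(ai))
      }, integer(1))
      k <- k + 1L
      rec_geno[[k]] <- dos
      rec_sites[[k]] <- data.frame(chrom = fix$CHROM[i],
                                   pos = as.numeric(fix$POS[i]),
                                   ref = fix$REF[i], alt = alts[ai],
                                   dp = info_dp[i], qual = qual[i],
                                   stringsAsFactors = FALSE)
    }
  }
  if (k == 0L) stop("no usable variant records in ", path)
  geno <- do.call(cbind, rec_geno)
  sites <- do.call(rbind, rec_sites)
  samples <- data.frame(id = vcf_samples, stringsAsFactors = FALSE)
  if (!is.null(sample_labels)) {
    m <- match(samples$id, sample_labels$id)
    samples$sex <- ifelse(is.na(m), "unknown", sample_labels$sex[m])
    samples$subgroup <- ifelse(is.na(m), "other", sample_labels$subgroup[m])
  }
  geno_matrix(geno, sites, samples)
}

#' Write a genotype matrix as a plain-text VCF
#'
#' Emits minimal VCF 4.2 with GT genotypes, site DP in INFO and site quality
#' in QUAL; intended for serialising simulated panels as text fixtures.
#'
#' @param gm a [geno_matrix()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "geno_matrix"))
  st <- gm$sites
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  g <- gm$geno
  body <- vapply(seq_len(ncol(g)), function(j) {
    gts <- ifelse(is.na(g[, j]), "./.", gt_code[as.character(g[, j])])
    dp <- if (is.na(st$dp[j])) "." else paste0("DP=", st$dp[j])
    qual <- if (is.na(st$qual[j])) "." else format(st$qual[j])
    paste(c(st$chrom[j], format(st$pos[j], scientific = FALSE),
            ".", st$ref[j] %||% "A", st$alt[j] %||% "T", qual, "PASS",
            dp, "GT", gts), collapse = "\t")
  }, character(1))
  header <- c("##fileformat=VCFv4.2",
              "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", gm$samples$id), collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a sample-label table
#'
#' @param path TSV with header columns `id`, `sex`, `subgroup`
#' @return data.frame
#' @export
read_labels <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("id", "sex", "subgroup") %in% names(tab)))
  tab
}

#' Read a W-Z anchor gene-pair table
#'
#' @param path TSV with header columns `w_gene`, `w_chrom`, `w_start`,
#'   `w_end`, `z_gene`, `z_chrom`, `z_start`, `z_end` (optional `block`)
#' @return data.frame of anchor pairs
#' @export
read_anchors <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("w_gene", "w_chrom", "w_start", "w_end",
            "z_gene", "z_chrom", "z_start", "z_end")
  stopifnot(all(need %in% names(tab)))
  tab
}

#' Read a genetic-map marker table
#'
#' @param path TSV with header columns `map_id`, `chrom`, `pos_bp`, `pos_cm`
#' @return data.frame of markers
#' @export
read_map <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "pos_bp", "pos_cm") %in% names(tab)))
  if (any(tab$pos_cm < 0)) stop("genetic positions (cM) must be >= 0")
  tab
}
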