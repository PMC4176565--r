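# Readers and writers for the standard formats the pipeline touches.
# This module is the single home for coordinate-dialect conversions:
# everything in memory is 0-based half-open; GFF3 is 1-based inclusive on
# disk; BED and bedGraph are 0-based half-open on disk.

IUPAC_DNA <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
               "B", "D", "H", "V", "N")

#' Read a genome FASTA
#'
#' Sequences are case-folded to uppercase and validated against the IUPAC DNA
#' alphabet; any other letter is a format error.
#'
#' @param path FASTA file.
#' @return a named character vector of chromosome sequences, with an attribute
#'   `chrom_lengths` (named integer vector).
#' @export
read_genome_fasta <- function(path) {
  assert_that(file.exists(path), paste0("no such file: ", path))
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) rlang::abort(paste0("malformed FASTA: ", conditionMessage(e))))
  seqs <- toupper(as.character(set))
  assert_that(length(seqs) > 0, "FASTA contains no records")
  assert_that(!anyDuplicated(names(seqs)), "duplicate chromosome names in FASTA")
  assert_that(all(nchar(seqs) > 0), "FASTA contains an empty record")
  for (i in seq_along(seqs)) {
    letters <- unique(strsplit(seqs[[i]], "", fixed = TRUE)[[1]])
    bad <- setdiff(letters, IUPAC_DNA)
    if (length(bad) > 0) {
      rlang::abort(paste0("record '", names(seqs)[i],
                          "' contains non-IUPAC DNA letter(s): ",
                          paste(bad, collapse = ", ")))
    }
  }
  genome_seq(seqs)
}

genome_seq <- function(seqs) {
  structure(seqs,
            chrom_lengths = stats::setNames(nchar(seqs), names(seqs)),
            class = c("genome_seq", "character"))
}

#' @export
print.genome_seq <- function(x, ...) {
  cat("<genome_seq> ", length(x), " chromosome(s), ",
      format(sum(nchar(x)), big.mark = ","), " bp\n", sep = "")
  invisible(x)
}

#' Chromosome lengths of a genome
#' @param genome a `genome_seq` from [read_genome_fasta()].
#' @return named integer vector.
#' @export
chrom_lengths <- function(genome) attr(genome, "chrom_lengths")

#' Write a genome FASTA
#' @param genome a `genome_seq`.
#' @param path output file.
#' @param width line width.
#' @export
write_genome_fasta <- function(genome, path, width = 70L) {
  set <- Biostrings::DNAStringSet(unclass(genome)[seq_along(genome)])
  names(set) <- names(genome)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read gene annotations from a GFF3 file
#'
#' Only features of type `gene` are kept; 1-based inclusive GFF coordinates
#' are converted to 0-based half-open. The gene id is taken from the `ID=`
#' attribute (falling back to `Name=`).
#'
#' @param path GFF3 file.
#' @return tibble with `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
read_gff_genes <- function(path) {
  assert_that(file.exists(path), paste0("no such file: ", path))
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0) return(tibble::tibble(
    gene_id = character(), chrom = character(),
    start = integer(), end = integer(), strand = character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 9L)
  assert_that(length(bad) == 0,
              paste0("GFF line ", bad[1], " does not have 9 tab-separated fields"))
  m <- do.call(rbind, fields)
  keep <- m[, 3] == "gene"
  m <- m[keep, , drop = FALSE]
  if (nrow(m) == 0) return(read_gff_genes_empty())
  start1 <- suppressWarnings(as.integer(m[, 4]))
  end1 <- suppressWarnings(as.integer(m[, 5]))
  assert_that(!anyNA(start1) && !anyNA(end1), "non-numeric GFF coordinates")
  assert_that(all(start1 <= end1), "GFF gene with start > end")
  strand <- m[, 7]
  assert_that(all(strand %in% c("+", "-")),
              "gene feature with missing or invalid strand")
  ids <- stringr::str_match(m[, 9], "(?:^|;)\\s*(?:ID|Name)=([^;]+)")[, 2]
  ids[is.na(ids)] <- paste0("gene_", which(is.na(ids)))
  out <- tibble::tibble(gene_id = ids, chrom = m[, 1],
                        start = start1 - 1L, end = end1, strand = strand)
  assert_that(!anyDuplicated(out$gene_id), "duplicate gene ids in GFF")
  out
}

read_gff_genes_empty <- function() {
  tibble::tibble(gene_id = character(), chrom = character(),
                 start = integer(), end = integer(), strand = character())
}

#' Write gene annotations as GFF3
#' @param genes tibble as returned by [read_gff_genes()].
#' @param path output file.
#' @param source source column value.
#' @export
write_gff_genes <- function(genes, path, source = "orichrom") {
  header <- "##gff-version 3"
  body <- sprintf("%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                  genes$chrom, source, genes$start + 1L, genes$end,
                  genes$strand, genes$gene_id)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a replication-origin table
#'
#' Tab-delimited with a header line naming `name`, `chrom`, `acs_start`,
#' `acs_end`, `acs_strand` and `timing`. Coordinates are 0-based half-open;
#' `acs_strand` is the strand whose forward reading of the ACS is T-rich.
#' Timing values outside `early`/`late` are mapped to `unknown` with a
#' warning.
#'
#' @param path TSV file.
#' @param genome optional `genome_seq`; when supplied, ACS coordinates are
#'   validated against chromosome lengths.
#' @return tibble with one row per origin.
#' @export
read_origin_table <- function(path, genome = NULL) {
  assert_that(file.exists(path), paste0("no such file: ", path))
  tb <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("name", "chrom", "acs_start", "acs_end", "acs_strand", "timing")
  missing_cols <- setdiff(need, names(tb))
  assert_that(length(missing_cols) == 0,
              paste0("origin table lacks column(s): ", paste(missing_cols, collapse = ", ")))
  tb <- tb[need]
  assert_that(!anyDuplicated(tb$name),
              paste0("duplicate origin name(s): ",
                     paste(unique(tb$name[duplicated(tb$name)]), collapse = ", ")))
  assert_that(all(tb$acs_end - tb$acs_start >= 1), "ACS interval must span at least 1 bp")
  assert_that(all(tb$acs_strand %in% c("+", "-")), "acs_strand must be '+' or '-'")
  odd <- tb$timing %not_in% c("early", "late")
  if (any(odd)) {
    rlang::warn(paste0(sum(odd), " origin(s) with timing outside early/late mapped to 'unknown'"))
    tb$timing[odd] <- "unknown"
  }
  if (!is.null(genome)) {
    lens <- chrom_lengths(genome)
    assert_that(all(tb$chrom %in% names(lens)), "origin on unknown chromosome")
    assert_that(all(tb$acs_start >= 0 & tb$acs_end <= lens[tb$chrom]),
                "ACS coordinates beyond chromosome length")
  }
  tb$acs_start <- as.integer(tb$acs_start)
  tb$acs_end <- as.integer(tb$acs_end)
  tb
}

#' Write a replication-origin table
#' @param origins origin tibble.
#' @param path output TSV.
#' @export
write_origin_table <- function(origins, path) {
  readr::write_tsv(origins, path, progress = FALSE)
  invisible(path)
}

#' Read stranded reads from a BED file
#'
#' BED6 (or first 6 columns of a wider BED): chrom, start, end, name, score,
#' strand; 0-based half-open as BED mandates.
#'
#' @param path BED file.
#' @return tibble with `chrom`, `start`, `end`, `strand`.
#' @export
read_bed_reads <- function(path) {
  assert_that(file.exists(path), paste0("no such file: ", path))
  tb <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE, progress = FALSE)
  assert_that(ncol(tb) >= 6, "read BED needs 6 columns (strand in column 6)")
  out <- tibble::tibble(chrom = as.character(tb[[1]]), start = as.integer(tb[[2]]),
                        end = as.integer(tb[[3]]), strand = as.character(tb[[6]]))
  assert_that(all(out$strand %in% c("+", "-")), "BED strand must be '+' or '-'")
  assert_that(all(out$start < out$end), "BED interval with start >= end")
  out
}

#' Write stranded reads as BED6
#' @param reads tibble with `chrom`, `start`, `end`, `strand`.
#' @param path output file.
#' @export
write_bed_reads <- function(reads, path) {
  writeLines(sprintf("%s\t%d\t%d\tread%d\t0\t%s",
                     reads$chrom, reads$start, reads$end,
                     seq_len(nrow(reads)), reads$strand), path)
  invisible(path)
}

#' Write a coverage track as bedGraph
#'
#' Intervals are 0-based half-open; runs of adjacent equal values are merged.
#' Values are written with full precision so that a write/read round trip is
#' value-exact at every base.
#'
#' @param track a `coverage_track`.
#' @param path output file.
#' @export
write_bedgraph <- function(track, path) {
  for (chr in names(track$values)) {
    assert_that(!anyNA(track$values[[chr]]) && all(is.finite(track$values[[chr]])),
                paste0("non-finite value in track on ", chr))
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (chr in names(track$values)) {
    v <- track$values[[chr]]
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    writeLines(paste(chr, starts, ends,
                     format(r$values, digits = 17, trim = TRUE, scientific = FALSE)),
               con, sep = "\n")
  }
  invisible(path)
}

#' Read a bedGraph into a coverage track
#' @param path bedGraph file.
#' @param chrom_lengths named integer vector; bases not covered by any
#'   interval are set to 0.
#' @return a `coverage_track` (not marked normalized).
#' @export
read_bedgraph <- function(path, chrom_lengths) {
  assert_that(file.exists(path), paste0("no such file: ", path))
  tb <- utils::read.table(path, sep = " ", col.names = c("chrom", "start", "end", "value"),
                          colClasses = c("character", "integer", "integer", "numeric"))
  values <- lapply(names(chrom_lengths), function(chr) {
    v <- numeric(chrom_lengths[[chr]])
    sub <- tb[tb$chrom == chr, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      v[(sub$start[i] + 1L):sub$end[i]] <- sub$value[i]
    }
    v
  })
  names(values) <- names(chrom_lengths)
  coverage_track(values)
}
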