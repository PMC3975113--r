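# Genome container and standard-format I/O.  One internal coordinate
# convention everywhere: 0-based half-open intervals; GFF3 (1-based
# inclusive) is converted at the boundary.  Gene span is the outermost
# gene-feature coordinates: the analysis operates at gene-model
# granularity, not mRNA/CDS structure.

#' Construct a Genome object
#'
#' A `Genome` bundles chromosome lengths, a sorted gene table, and
#' (optionally) protein and chromosome nucleotide sequences.
#'
#' @param chromosomes named numeric vector of chromosome lengths (bp).
#' @param genes data.frame with columns `gene_id`, `chrom`, `strand`
#'   (`"+"`/`"-"`), `start`, `end` (0-based half-open), `description`
#'   (`""` if none), `domain_hits` (list column of character vectors) and
#'   `protein_length` (aa, `NA` for non-coding).
#' @param proteins named character vector of amino-acid sequences, or `NULL`.
#' @param genomic_seq named [Biostrings::DNAStringSet] (or named character
#'   vector) of chromosome sequences, or `NULL`.
#' @return An object of class `"Genome"`.  Genes are re-sorted by
#'   `(chrom, start)`.
#' @export
new_genome <- function(chromosomes, genes, proteins = NULL, genomic_seq = NULL) {
  stopifnot(is.numeric(chromosomes), !is.null(names(chromosomes)))
  genes <- as.data.frame(genes)
  need <- c("gene_id", "chrom", "strand", "start", "end")
  miss <- setdiff(need, names(genes))
  if (length(miss)) stopf("genes table lacks column(s): %s", paste(miss, collapse = ", "))
  if (is.null(genes$description)) genes$description <- ""
  genes$description[is.na(genes$description)] <- ""
  if (is.null(genes$domain_hits)) genes$domain_hits <- replicate(nrow(genes), character(0), simplify = FALSE)
  if (is.null(genes$protein_length)) genes$protein_length <- NA_integer_
  if (anyDuplicated(genes$gene_id))
    stopf("duplicate gene_id: %s", genes$gene_id[duplicated(genes$gene_id)][1])
  bad <- which(!(genes$start >= 0 & genes$start < genes$end))
  if (length(bad)) stopf("gene %s violates 0 <= start < end", genes$gene_id[bad[1]])
  if (!all(genes$strand %in% c("+", "-")))
    stopf("strand must be '+' or '-'")
  unk <- setdiff(unique(genes$chrom), names(chromosomes))
  if (length(unk)) stopf("gene on unknown chromosome: %s", unk[1])
  over <- which(genes$end > chromosomes[genes$chrom])
  if (length(over)) stopf("gene %s extends beyond its chromosome", genes$gene_id[over[1]])
  genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  if (!is.null(genomic_seq) && is.character(genomic_seq))
    genomic_seq <- Biostrings::DNAStringSet(genomic_seq)
  structure(
    list(chromosomes = chromosomes, genes = genes,
         proteins = proteins, genomic_seq = genomic_seq),
    class = "Genome"
  )
}

#' @export
print.Genome <- function(x, ...) {
  cat(sprintf("Genome: %d chromosome(s), %d gene(s)%s%s\n",
              length(x$chromosomes), nrow(x$genes),
              if (!is.null(x$proteins)) sprintf(", %d protein(s)", length(x$proteins)) else "",
              if (!is.null(x$genomic_seq)) ", with nucleotide sequence" else ""))
  invisible(x)
}

#' Read gene models from a GFF3 file
#'
#' Only `gene` features are used (feature hierarchies are out of scope).
#' Coordinates are converted from GFF3 1-based inclusive to the internal
#' 0-based half-open convention.  Descriptions are taken from the `Note`
#' or `description` attribute (empty string when absent); domain hits from
#' a comma-separated `domain_hits` attribute; protein length from a
#' `protein_length` attribute.
#'
#' @param path GFF3 file path.
#' @return A [new_genome()] `Genome` (genes only; no sequences attached).
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- which(!grepl("^\\s*(#|$)", lines))
  for (i in body) {
    nf <- length(strsplit(lines[i], "\t", fixed = TRUE)[[1]])
    if (nf != 9) stopf("GFF3 parse error at line %d: %d field(s), expected 9", i, nf)
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) stopf("GFF3 parse error in '%s': %s", path, conditionMessage(e))
  )
  gr <- gr[gr$type == "gene"]
  md <- S4Vectors::mcols(gr)
  get_attr <- function(nm) {
    if (!nm %in% names(md)) return(rep(NA_character_, length(gr)))
    v <- md[[nm]]
    if (methods::is(v, "CharacterList") || is.list(v))
      v <- vapply(v, function(x) if (length(x)) paste(x, collapse = ",") else NA_character_, "")
    as.character(v)
  }
  ids <- get_attr("ID")
  if (anyNA(ids)) stopf("GFF3 gene feature without ID attribute in '%s'", path)
  if (anyDuplicated(ids)) stopf("duplicate gene ID in '%s': %s", path, ids[duplicated(ids)][1])
  desc <- get_attr("Note")
  d2 <- get_attr("description")
  desc[is.na(desc)] <- d2[is.na(desc)]
  desc[is.na(desc)] <- ""
  hits <- get_attr("domain_hits")
  hits <- lapply(hits, function(h) if (is.na(h) || h == "") character(0) else strsplit(h, ",", fixed = TRUE)[[1]])
  plen <- suppressWarnings(as.integer(get_attr("protein_length")))
  genes <- data.frame(
    gene_id = ids,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = ifelse(as.character(GenomicRanges::strand(gr)) == "-", "-", "+"),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    description = desc,
    stringsAsFactors = FALSE
  )
  genes$domain_hits <- hits
  genes$protein_length <- plen
  sl <- GenomeInfoDb_seqlengths(gr)
  # honour ##sequence-region directives (not all writers/readers carry
  # them through GRanges seqinfo)
  sr <- grep("^##sequence-region\\s", lines, value = TRUE)
  if (length(sr)) {
    parts <- strsplit(trimws(sr), "\\s+")
    srl <- stats::setNames(vapply(parts, function(p) as.numeric(p[4]), 0),
                           vapply(parts, function(p) p[2], ""))
    sl <- c(srl, sl[setdiff(names(sl), names(srl))])
  }
  chroms <- union(unique(genes$chrom), names(sl)[!is.na(sl)])
  lens <- stats::setNames(rep(NA_real_, length(chroms)), chroms)
  known <- intersect(names(sl)[!is.na(sl)], names(lens))
  lens[known] <- sl[known]
  nas <- is.na(lens)
  if (any(nas)) {
    mx <- tapply(genes$end, genes$chrom, max)
    lens[nas] <- mx[names(lens)[nas]]
  }
  if (nrow(genes) == 0)
    return(new_genome(stats::setNames(numeric(0), character(0)), genes))
  new_genome(lens, genes)
}

# Chromosome lengths of a GRanges as a plain named vector.
GenomeInfoDb_seqlengths <- function(gr) {
  sl <- tryCatch(GenomeInfoDb::seqinfo(gr), error = function(e) NULL)
  if (is.null(sl)) return(stats::setNames(numeric(0), character(0)))
  stats::setNames(as.numeric(GenomeInfoDb::seqlengths(sl)), GenomeInfoDb::seqnames(sl))
}

#' Write gene models to GFF3
#'
#' Inverse of [read_gff3()]: internal 0-based half-open coordinates are
#' converted back to GFF3 1-based inclusive.
#'
#' @param genome a `Genome`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genome, path) {
  g <- genome$genes
  sl <- genome$chromosomes
  gr <- GenomicRanges::GRanges(
    seqnames = g$chrom,
    ranges = IRanges::IRanges(start = g$start + 1L, end = g$end),
    strand = g$strand
  )
  GenomeInfoDb::seqlengths(gr) <- sl[GenomeInfoDb::seqlevels(gr)]
  gr$type <- "gene"
  gr$ID <- g$gene_id
  note <- g$description
  note[note == ""] <- NA_character_
  gr$Note <- note
  dh <- vapply(g$domain_hits, function(h) if (length(h)) paste(h, collapse = ",") else NA_character_, "")
  gr$domain_hits <- dh
  gr$protein_length <- ifelse(is.na(g$protein_length), NA_character_, as.character(g$protein_length))
  rtracklayer::export(gr, path, format = "gff3")
  # add ##sequence-region directives so chromosome lengths round-trip
  lines <- readLines(path, warn = FALSE)
  sr <- sprintf("##sequence-region %s 1 %.0f", names(sl), sl)
  first_body <- which(!grepl("^#", lines))[1]
  if (is.na(first_body)) first_body <- length(lines) + 1
  writeLines(c(lines[seq_len(first_body - 1)], sr,
               lines[seq(first_body, length.out = length(lines) - first_body + 1)]),
             path)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#'
#' @param path FASTA file path.
#' @param type `"protein"` or `"dna"`.
#' @return Named character vector; names are the first whitespace-delimited
#'   token of each header.
#' @export
read_fasta <- function(path, type = c("protein", "dna")) {
  type <- match.arg(type)
  ss <- if (type == "protein") Biostrings::readAAStringSet(path)
        else Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids))
    stopf("duplicate FASTA id in '%s': %s", path, ids[duplicated(ids)][1])
  stats::setNames(as.character(ss), ids)
}

#' Write a named character vector of sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output file path.
#' @param type `"protein"` or `"dna"`.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, type = c("protein", "dna")) {
  type <- match.arg(type)
  ss <- if (type == "protein") Biostrings::AAStringSet(seqs)
        else Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read an expression matrix from TSV
#'
#' First column is the gene id; remaining columns are per-condition
#' intensities (non-negative).
#'
#' @param path TSV file path.
#' @return Numeric matrix, genes in rows (rownames), conditions in columns.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stopf("expression table '%s' needs >= 1 numeric column", path)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stopf("duplicate gene_id in '%s': %s", path, ids[duplicated(ids)][1])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  bad <- which(is.na(m), arr.ind = TRUE)
  if (nrow(bad))
    stopf("missing value in '%s' at gene %s, column %s", path,
          ids[bad[1, 1]], colnames(m)[bad[1, 2]])
  neg <- which(m < 0, arr.ind = TRUE)
  if (nrow(neg))
    stopf("negative intensity in '%s' at gene %s, column %s", path,
          ids[neg[1, 1]], colnames(m)[neg[1, 2]])
  m
}

#' Write an expression matrix to TSV
#'
#' @param mat numeric matrix with gene rownames.
#' @param path output file path.
#' @param id_col name of the gene-id column.
#' @return `path`, invisibly.
#' @export
write_expression <- function(mat, path, id_col = "gene_id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write clusters (or super-clusters) to BED
#'
#' Internal coordinates are already BED's 0-based half-open convention, so
#' spans are written verbatim, one row per cluster, name column = cluster id.
#'
#' @param clusters list of clusters as returned by [call_clusters()] or
#'   [call_superclusters()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(clusters, path) {
  if (length(clusters) == 0) {
    file.create(path)
    return(invisible(path))
  }
  df <- data.frame(
    chrom = vapply(clusters, `[[`, "", "chrom"),
    start = vapply(clusters, function(cl) cl$span[1], 0),
    end = vapply(clusters, function(cl) cl$span[2], 0),
    name = vapply(clusters, function(cl) cl$cluster_id %||% cl$sc_id, "")
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a phylogenetic tree to Newick
#'
#' @param tree an [ape::phylo] tree.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 10)
  invisible(path)
}

#' Read a Newick tree
#'
#' @param path Newick file path.
#' @return An [ape::phylo] tree.
#' @export
read_newick <- function(path) ape::read.tree(path)
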