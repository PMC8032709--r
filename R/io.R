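#' Read a samples x markers genotype table
#'
#' Tab-separated table: first column sample ids, remaining columns marker
#' dosages coded 0/1/2 or NA for missing.
#'
#' @param path TSV file path.
#' @return Integer matrix with sample rownames and marker colnames.
#' @export
read_genotype_table <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop_clonediv("genotype table needs sample + markers",
                                  "parse_error")
  m <- as.matrix(df[, -1, drop = FALSE])
  bad <- which(!(m %in% c("0", "1", "2", NA, 0, 1, 2)))
  if (length(bad) > 0) {
    row <- ((bad[1] - 1) %% nrow(m)) + 1
    stop_clonediv(sprintf("invalid dosage at data line %d", row),
                  "parse_error")
  }
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1]]
  m
}

#' Write a genotype table
#'
#' @param m samples x markers dosage matrix.
#' @param path output TSV path.
#' @export
write_genotype_table <- function(m, path) {
  df <- data.frame(sample = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

map_vcf_gt <- function(gt) {
  core <- sub(":.*", "", gt)
  core <- gsub("\\|", "/", core)
  out <- rep(NA_character_, length(core))
  out[core %in% c("0/0")] <- "hom_ref"
  out[core %in% c("0/1", "1/0")] <- "het"
  out[core %in% c("1/1")] <- "hom_alt"
  out
}

#' Read a caller's multi-sample VCF into a call set
#'
#' Parses a VCF (one per caller; GT genotypes per clone sample) into the
#' `call_set` layout used by [intersect_callers()]. Multiallelic records
#' (comma in ALT) and non-SNV records are rejected: the pipeline considers
#' biallelic single-nucleotide variants only.
#'
#' @param path VCF file path.
#' @param caller caller name for the call set.
#' @return A `call_set`.
#' @export
read_caller_vcf <- function(path, caller = basename(path)) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix)          # single-record VCF
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  if (any(grepl(",", fix$ALT))) {
    stop_clonediv("multiallelic records are not supported; split or drop them",
                  "multiallelic_record")
  }
  if (any(nchar(fix$REF) != 1 | nchar(fix$ALT) != 1)) {
    stop_clonediv("only single-nucleotide variants are supported",
                  "invalid_record")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  clones <- colnames(gt)
  calls <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                      ref = toupper(fix$REF), alt = toupper(fix$ALT))
  for (cl in clones) calls[[paste0("gt_", cl)]] <- map_vcf_gt(gt[, cl])
  calls <- calls[order(calls$chrom, calls$pos), , drop = FALSE]
  rownames(calls) <- NULL
  structure(list(caller = caller, calls = calls, clones = clones),
            class = "call_set")
}

#' Write a call set as a minimal multi-sample VCF
#'
#' @param callset a `call_set`.
#' @param path output path (plain-text VCF 4.2 with GT-only genotypes).
#' @export
write_call_vcf <- function(callset, path) {
  gt_map <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1")
  calls <- callset$calls
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=clonediv",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", callset$clones), collapse = "\t")),
             con)
  if (nrow(calls) > 0) {
    gt_cols <- paste0("gt_", callset$clones)
    cols <- c(list(calls$chrom, as.character(calls$pos), ".", calls$ref,
                   calls$alt, ".", "PASS", ".", "GT"),
              lapply(gt_cols, function(cc) unname(gt_map[calls[[cc]]])))
    writeLines(do.call(paste, c(cols, sep = "\t")), con)
  }
  invisible(path)
}

#' Write coded sequences to FASTA
#'
#' @param seqs coded sequence matrix ([code_genotypes()]).
#' @param path output FASTA path.
#' @export
write_coded_fasta <- function(seqs, path) {
  seqinr::write.fasta(lapply(seq_len(nrow(seqs)), function(i) seqs[i, ]),
                      names = rownames(seqs), file.out = path)
  invisible(path)
}

#' Read coded sequences from FASTA
#'
#' @param path FASTA path.
#' @return Coded sequence matrix.
#' @export
read_coded_fasta <- function(path) {
  s <- seqinr::read.fasta(path, as.string = FALSE, forceDNAtolower = FALSE)
  m <- do.call(rbind, lapply(s, as.character))
  rownames(m) <- names(s)
  toupper(m)
}

#' Write a median-joining network as an edge list and NEXUS network block
#'
#' @param net an `mj_network`.
#' @param edges_path output TSV path for the edge list (from, to, steps,
#'   from_is_median, to_is_median).
#' @param nexus_path optional path for a NEXUS `Network` block.
#' @export
write_network <- function(net, edges_path, nexus_path = NULL) {
  e <- net$edges
  e$from_is_median <- net$is_median[e$from]
  e$to_is_median <- net$is_median[e$to]
  write.table(e, edges_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(nexus_path)) {
    con <- file(nexus_path, "w")
    on.exit(close(con))
    writeLines("#NEXUS", con)
    writeLines(sprintf("[median-joining network, epsilon = %g]",
                       net$epsilon), con)
    writeLines("BEGIN Network;", con)
    writeLines(sprintf("  DIMENSIONS nvertices=%d nedges=%d;",
                       nrow(net$nodes), nrow(e)), con)
    writeLines("  VERTICES", con)
    writeLines(sprintf("    %d %s%s,", seq_len(nrow(net$nodes)),
                       rownames(net$nodes),
                       ifelse(net$is_median, " [median]", "")), con)
    writeLines("  ;", con)
    writeLines("  EDGES", con)
    idx <- setNames(seq_len(nrow(net$nodes)), rownames(net$nodes))
    writeLines(sprintf("    %d %d %d steps=%d,", seq_len(nrow(e)),
                       idx[e$from], idx[e$to], e$steps), con)
    writeLines("  ;", con)
    writeLines("END;", con)
  }
  invisible(edges_path)
}

#' Write / read a Newick tree
#'
#' Thin wrappers around [ape::write.tree()] / [ape::read.tree()]; bootstrap
#' supports travel as internal node labels.
#'
#' @param phy an [ape::phylo] tree.
#' @param path file path.
#' @return `read_newick` returns an [ape::phylo].
#' @export
write_newick <- function(phy, path) {
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}
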