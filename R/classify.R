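#' Classify one site's clone genotype pattern
#'
#' Partitions a per-clone genotype vector (relative to an assumed
#' homozygous-reference reference genome) into the cultivar-level and
#' clone-level variant classes:
#' \describe{
#'   \item{SNP}{all clones share one identical non-reference genotype
#'     (cultivar-level polymorphism against the reference genome).}
#'   \item{SC_het}{exactly one clone heterozygous, the rest homozygous
#'     reference.}
#'   \item{SC_ref}{exactly one clone homozygous reference, the rest sharing
#'     the same heterozygous genotype.}
#'   \item{SC_hom}{exactly one clone homozygous alternative, the rest sharing
#'     one genotype (heterozygous or homozygous reference).}
#'   \item{Sh_het / Sh_hom}{a 2+2 split into exactly two genotype states;
#'     focal = the pair carrying the more alternative state (`Sh_hom` when
#'     that pair is homozygous alternative, `Sh_het` otherwise).}
#'   \item{complex}{three or more distinct genotype states, or a two-state
#'     pattern matching none of the above.}
#' }
#' The single-clone (SC) focal set is always the one clone whose genotype
#' differs from the other three.
#'
#' @param genotypes named character vector (one entry per clone) over
#'   `c("hom_ref", "het", "hom_alt")`. The class system is defined for four
#'   clones; other sizes are accepted but only all-same and one-vs-rest
#'   patterns generalise.
#' @return List with `class` and `focal` (character vector of clone ids,
#'   length 1 for SC, 2 for Sh, 0 otherwise).
#' @export
classify_site <- function(genotypes) {
  if (is.null(names(genotypes)) || any(!nzchar(names(genotypes)))) {
    stop_clonediv("genotypes must be named by clone", "invalid_argument")
  }
  if (!all(genotypes %in% GT_LEVELS)) {
    stop_clonediv("genotypes must be hom_ref, het or hom_alt",
                  "invalid_argument")
  }
  n <- length(genotypes)
  if (n < 2) stop_clonediv("need at least two clones", "invalid_argument")
  states <- unique(genotypes)

  if (length(states) == 1) {
    if (states == "hom_ref") {
      stop_clonediv("all clones homozygous reference: invariant site",
                    "invariant_site")
    }
    return(list(class = "SNP", focal = character(0)))
  }
  if (length(states) > 2) return(list(class = "complex", focal = character(0)))

  counts <- sort(table(genotypes), decreasing = TRUE)
  minority_state <- names(counts)[length(counts)]
  majority_state <- names(counts)[1]

  if (counts[length(counts)] == 1) {           # one clone vs the rest
    focal <- names(genotypes)[genotypes == minority_state]
    cls <- if (minority_state == "het" && majority_state == "hom_ref") {
      "SC_het"
    } else if (minority_state == "hom_ref" && majority_state == "het") {
      "SC_ref"
    } else if (minority_state == "hom_alt") {
      "SC_hom"
    } else {
      "complex"                                # e.g. het against hom_alt
    }
    if (cls == "complex") focal <- character(0)
    return(list(class = cls, focal = focal))
  }
  if (n == 4 && all(counts == 2)) {            # 2+2 split, two states
    dosage <- c(hom_ref = 0, het = 1, hom_alt = 2)
    alt_state <- if (dosage[states[1]] > dosage[states[2]]) states[1] else
      states[2]
    focal <- sort(names(genotypes)[genotypes == alt_state])
    cls <- if (alt_state == "hom_alt") "Sh_hom" else "Sh_het"
    return(list(class = cls, focal = focal))
  }
  list(class = "complex", focal = character(0))
}

#' Partition a variant collection into classes
#'
#' Applies [classify_site()] to every row of a genotype-vector table and
#' tallies a classification summary (counts per class, transition/transversion
#' counts and their ratio, optionally counts per genomic region when a gene
#' model is supplied).
#'
#' @param vs data frame with columns `chrom`, `pos`, `ref`, `alt` and one
#'   `gt_<clone>` column per clone (the layout of a `call_set`'s `calls`).
#' @param gene_model optional [gene_model()] for region annotation.
#' @return List of class `classification`: `variants` (input plus `class`,
#'   `focal`, `substitution`, and `region` when annotated) and `summary`
#'   (list: `class_counts`, `n`, `tstv`, `region_table`).
#' @export
partition_variants <- function(vs, gene_model = NULL) {
  key <- paste(vs$chrom, vs$pos, vs$ref, vs$alt, sep = ":")
  if (anyDuplicated(key)) {
    stop_clonediv("duplicate site keys in input", "duplicate_input")
  }
  gt_cols <- grep("^gt_", names(vs), value = TRUE)
  clones <- sub("^gt_", "", gt_cols)
  cls <- character(nrow(vs)); focal <- character(nrow(vs))
  for (i in seq_len(nrow(vs))) {
    g <- setNames(vapply(gt_cols, function(cc) as.character(vs[[cc]][i]),
                         character(1)), clones)
    r <- classify_site(g)
    cls[i] <- r$class
    focal[i] <- paste(r$focal, collapse = ",")
  }
  out <- vs
  out$class <- cls
  out$focal <- focal
  out$substitution <- substitution_type(vs$ref, vs$alt)
  if (!is.null(gene_model)) {
    out$region <- annotate_region(vs$chrom, vs$pos, gene_model)
  }
  all_classes <- c("SNP", "SC_het", "SC_ref", "SC_hom", "Sh_het", "Sh_hom",
                   "complex")
  class_counts <- table(factor(cls, levels = all_classes))
  n_ts <- sum(out$substitution == "transition")
  n_tv <- sum(out$substitution == "transversion")
  summary <- list(
    n = nrow(out),
    class_counts = class_counts,
    n_snv = sum(class_counts[c("SC_het", "SC_ref", "SC_hom",
                               "Sh_het", "Sh_hom")]),
    n_transitions = n_ts, n_transversions = n_tv,
    tstv = if (n_tv > 0) n_ts / n_tv else NA_real_,
    region_table = if (!is.null(gene_model)) {
      table(out$region, out$substitution)
    } else NULL
  )
  structure(list(variants = out, summary = summary), class = "classification")
}

#' Gene model for region annotation
#'
#' A minimal interval gene model: gene spans and exon intervals per
#' chromosome, 1-based inclusive coordinates. Exons must lie within gene
#' spans; intervals are sorted internally so annotation is independent of
#' insertion order.
#'
#' @param genes data frame with columns `chrom`, `start`, `end`.
#' @param exons data frame with columns `chrom`, `start`, `end`.
#' @return Object of class `gene_model`.
#' @export
gene_model <- function(genes, exons) {
  stopifnot(all(c("chrom", "start", "end") %in% names(genes)),
            all(c("chrom", "start", "end") %in% names(exons)))
  if (any(genes$end < genes$start) || any(exons$end < exons$start)) {
    stop_clonediv("interval ends must not precede starts", "invalid_argument")
  }
  genes <- genes[order(genes$chrom, genes$start), c("chrom", "start", "end")]
  exons <- exons[order(exons$chrom, exons$start), c("chrom", "start", "end")]
  structure(list(genes = genes, exons = exons), class = "gene_model")
}

#' Read a gene model from a GFF3 file
#'
#' Extracts `gene` and `exon` features from a GFF3 (or GFF3-subset) file into
#' a [gene_model()].
#'
#' @param path GFF3 file path.
#' @return A `gene_model`.
#' @export
read_gene_model <- function(path) {
  g <- ape::read.gff(path)
  gene_model(
    genes = g[tolower(g$type) == "gene", c("seqid", "start", "end")] |>
      setNames(c("chrom", "start", "end")),
    exons = g[tolower(g$type) == "exon", c("seqid", "start", "end")] |>
      setNames(c("chrom", "start", "end"))
  )
}

in_intervals <- function(chrom, pos, ivl) {
  vapply(seq_along(chrom), function(i) {
    any(ivl$chrom == chrom[i] & ivl$start <= pos[i] & ivl$end >= pos[i])
  }, logical(1))
}

#' Annotate the genomic region of positions
#'
#' `exonic` if inside an exon interval (inclusive ends), `intronic` if inside
#' a gene span but not an exon, `intergenic` otherwise. Positions on unknown
#' chromosomes are `intergenic` with a warning (or an error in strict mode).
#'
#' @param chrom,pos vectors of chromosome names and 1-based positions.
#' @param model a [gene_model()].
#' @param strict error (instead of warn) on unknown chromosomes.
#' @return Character vector over `c("exonic", "intronic", "intergenic")`.
#' @export
annotate_region <- function(chrom, pos, model, strict = FALSE) {
  if (any(pos < 1)) stop_clonediv("positions are 1-based", "invalid_argument")
  known <- unique(c(model$genes$chrom, model$exons$chrom))
  unknown <- setdiff(unique(chrom), known)
  if (length(unknown) > 0) {
    msg <- paste("chromosomes absent from gene model:",
                 paste(unknown, collapse = ", "))
    if (strict) stop_clonediv(msg, "unknown_chrom") else warning(msg)
  }
  ex <- in_intervals(chrom, pos, model$exons)
  gn <- in_intervals(chrom, pos, model$genes)
  ifelse(ex, "exonic", ifelse(gn, "intronic", "intergenic"))
}

#' Transition or transversion
#'
#' A substitution is a transition when both alleles are purines (`A`, `G`) or
#' both pyrimidines (`C`, `T`); otherwise a transversion. Vectorised.
#'
#' @param ref,alt single-nucleotide alleles, `ref != alt`.
#' @return Character vector over `c("transition", "transversion")`.
#' @export
substitution_type <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  ok <- ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  if (!all(ok)) stop_clonediv("alleles must be single nucleotides A/C/G/T",
                              "invalid_allele")
  if (any(ref == alt)) stop_clonediv("ref and alt must differ",
                                     "invalid_allele")
  purine <- c("A", "G")
  ifelse((ref %in% purine) == (alt %in% purine), "transition", "transversion")
}

#' Transitions/transversions ratio of a marker set
#'
#' @param ref,alt allele vectors.
#' @return `n_transitions / n_transversions` (NA when no transversions).
#' @export
tstv_ratio <- function(ref, alt) {
  s <- substitution_type(ref, alt)
  n_tv <- sum(s == "transversion")
  if (n_tv == 0) return(NA_real_)
  sum(s == "transition") / n_tv
}
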