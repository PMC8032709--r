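#' Genotyping panel configuration
#'
#' @param panel_size total markers on the chip.
#' @param sc_quota single-clone (SC) SNV markers.
#' @param sh_quota shared (Sh) SNV markers; `sc_quota + sh_quota` must equal
#'   `panel_size`.
#' @param window_bp length (odd) of the assay sequence window centred on the
#'   target SNV.
#' @param clear_window_bp minimum variant-free distance around the target and
#'   inward from both window ends (probe/primer annealing zones).
#' @param per_clone_balance balance SC markers across focal clones.
#' @param chromosome_spread spread picks across chromosomes (greedy
#'   round-robin).
#' @param lineage_pairs list of two character vectors of clone ids; Sh
#'   markers whose focal pair equals either are prioritised (they separate
#'   the two propagation lineages).
#' @return Object of class `panel_config`.
#' @export
panel_config <- function(panel_size = 48, sc_quota = 42, sh_quota = 6,
                         window_bp = 601, clear_window_bp = 50,
                         per_clone_balance = TRUE, chromosome_spread = TRUE,
                         lineage_pairs = list(c("MB53", "MB59"),
                                              c("C143", "C225"))) {
  if (sc_quota + sh_quota != panel_size) {
    stop_clonediv("sc_quota + sh_quota must equal panel_size",
                  "invalid_argument")
  }
  if (window_bp %% 2 == 0) stop_clonediv("window_bp must be odd",
                                         "invalid_argument")
  if (window_bp < 2 * clear_window_bp + 1) {
    stop_clonediv("window shorter than 2 * clear_window_bp + 1",
                  "invalid_window")
  }
  structure(list(panel_size = panel_size, sc_quota = sc_quota,
                 sh_quota = sh_quota, window_bp = window_bp,
                 clear_window_bp = clear_window_bp,
                 per_clone_balance = per_clone_balance,
                 chromosome_spread = chromosome_spread,
                 lineage_pairs = lineage_pairs),
            class = "panel_config")
}

#' Is a marker candidate's flanking window clear?
#'
#' TRUE iff no neighbouring variant lies strictly within `clear_window_bp` of
#' the target position or strictly within `clear_window_bp` of either window
#' end (a neighbour exactly at the clearance distance passes: exclusive
#' boundary). Neighbours outside the window are ignored.
#'
#' @param target_pos target SNV position.
#' @param neighbor_pos positions of other variants (same chromosome).
#' @param config a [panel_config()].
#' @return Logical scalar.
#' @export
flank_is_clear <- function(target_pos, neighbor_pos,
                           config = panel_config()) {
  half <- (config$window_bp - 1) / 2
  w_start <- target_pos - half
  w_end <- target_pos + half
  nb <- neighbor_pos[neighbor_pos >= w_start & neighbor_pos <= w_end &
                       neighbor_pos != target_pos]
  if (length(nb) == 0) return(TRUE)
  cw <- config$clear_window_bp
  near_target <- abs(nb - target_pos) < cw
  near_ends <- (nb - w_start) < cw | (w_end - nb) < cw
  !any(near_target | near_ends)
}

#' Select a genotyping-chip marker panel
#'
#' Chooses `sc_quota` single-clone and `sh_quota` shared SNV markers from a
#' classified variant table, using the chip design criteria: only
#' heterozygous-alternative variants (`SC_het`, `Sh_het`) are assayable; each
#' candidate's flanking window must be free of neighbouring variants
#' ([flank_is_clear()]); SC markers are balanced across focal clones
#' ("equivalent number of variants for each clone"); Sh markers are
#' prioritised when their focal pair separates the two propagation lineages;
#' picks are spread across chromosomes by greedy round-robin. Selection is
#' deterministic for a fixed seed. Unsatisfiable quotas raise an
#' `infeasible_panel` error naming the shortfall.
#'
#' @param candidates data frame of classified variants: columns `chrom`,
#'   `pos`, `ref`, `alt`, `class`, `focal` (comma-joined clone ids). All rows
#'   (any class) count as neighbours for flank clearance.
#' @param config a [panel_config()].
#' @param seed integer seed (tie-breaking shuffle).
#' @return Data frame: `marker_id`, `chrom`, `pos`, `ref`, `alt`, `class`,
#'   `focal`.
#' @export
select_panel <- function(candidates, config = panel_config(), seed = 1L) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))

  clear <- vapply(seq_len(nrow(candidates)), function(i) {
    same <- candidates$pos[candidates$chrom == candidates$chrom[i]]
    flank_is_clear(candidates$pos[i], same, config)
  }, logical(1))
  elig <- candidates[clear & candidates$class %in% c("SC_het", "Sh_het"), ,
                     drop = FALSE]
  # deterministic seeded shuffle, then stable ordering by chrom/pos
  elig <- elig[sample.int(nrow(elig)), , drop = FALSE]

  round_robin <- function(df, k) {
    # greedy chromosome spread: cycle over chromosomes taking one at a time
    if (!config$chromosome_spread) return(head(df, k))
    picked <- integer(0)
    remaining <- seq_len(nrow(df))
    while (length(picked) < k && length(remaining) > 0) {
      for (ch in unique(df$chrom[remaining])) {
        if (length(picked) >= k) break
        i <- remaining[df$chrom[remaining] == ch][1]
        picked <- c(picked, i)
        remaining <- setdiff(remaining, i)
      }
    }
    df[picked, , drop = FALSE]
  }

  sc <- elig[elig$class == "SC_het", , drop = FALSE]
  sh <- elig[elig$class == "Sh_het", , drop = FALSE]

  shortfall <- character(0)
  sc_pick <- NULL
  if (config$per_clone_balance && nrow(sc) > 0) {
    by_clone <- split(sc, sc$focal)
    clones <- sort(names(by_clone))
    base <- config$sc_quota %/% length(clones)
    extra <- config$sc_quota %% length(clones)
    quotas <- setNames(rep(base, length(clones)), clones)
    if (extra > 0) quotas[seq_len(extra)] <- quotas[seq_len(extra)] + 1
    for (cl in clones) {
      have <- nrow(by_clone[[cl]])
      if (have < quotas[cl]) {
        shortfall <- c(shortfall, sprintf("SC for %s: need %d, have %d",
                                          cl, quotas[cl], have))
      }
    }
    if (length(shortfall) == 0) {
      sc_pick <- do.call(rbind, lapply(clones, function(cl)
        round_robin(by_clone[[cl]], quotas[cl])))
    }
  } else {
    if (nrow(sc) < config$sc_quota) {
      shortfall <- c(shortfall, sprintf("SC: need %d, have %d",
                                        config$sc_quota, nrow(sc)))
    } else sc_pick <- round_robin(sc, config$sc_quota)
  }

  pair_key <- function(x) vapply(strsplit(x, ","), function(p)
    paste(sort(p), collapse = ","), character(1))
  pri <- pair_key(sh$focal) %in%
    vapply(config$lineage_pairs, function(p) paste(sort(p), collapse = ","),
           character(1))
  sh <- sh[order(!pri), , drop = FALSE]        # lineage-separating pairs first
  if (nrow(sh) < config$sh_quota) {
    shortfall <- c(shortfall, sprintf("Sh: need %d, have %d",
                                      config$sh_quota, nrow(sh)))
  }
  if (length(shortfall) > 0) {
    stop_clonediv(paste0("panel quotas unsatisfiable: ",
                         paste(shortfall, collapse = "; ")),
                  "infeasible_panel")
  }
  sh_pick <- head(sh, config$sh_quota)

  panel <- rbind(sc_pick, sh_pick)
  panel <- panel[order(panel$class, panel$focal, panel$chrom, panel$pos), ,
                 drop = FALSE]
  grp <- gsub(",", "-", panel$focal)
  idx <- stats::ave(seq_along(grp), grp, FUN = seq_along)
  panel <- cbind(marker_id = sprintf("%s-snv%d", grp, idx),
                 panel[, c("chrom", "pos", "ref", "alt", "class", "focal"),
                       drop = FALSE])
  rownames(panel) <- NULL
  panel
}

#' Marker informativeness on a genotyped cohort
#'
#' For each marker of a samples x markers dosage matrix, counts the samples
#' carrying the alternative allele (dosage >= 1), flags the marker
#' informative when at least two samples carry it, and records which of the
#' three genotype states (0/1/2) occur. All-missing markers are flagged
#' unusable and excluded from carrier counts.
#'
#' @param m samples x markers matrix of dosages 0/1/2 (NA = missing).
#' @return Data frame: `marker`, `n_typed`, `carriers`, `informative`,
#'   `three_state`, `usable`.
#' @export
informativeness <- function(m) {
  if (is.null(dim(m)) || nrow(m) == 0 || ncol(m) == 0) {
    stop_clonediv("genotype matrix is empty", "invalid_argument")
  }
  res <- data.frame(
    marker = colnames(m) %||% sprintf("m%d", seq_len(ncol(m))),
    n_typed = colSums(!is.na(m)),
    carriers = colSums(m >= 1, na.rm = TRUE),
    row.names = NULL
  )
  res$usable <- res$n_typed > 0
  res$carriers[!res$usable] <- NA_integer_
  res$informative <- !is.na(res$carriers) & res$carriers >= 2
  res$three_state <- vapply(seq_len(ncol(m)), function(j)
    all(c(0, 1, 2) %in% m[, j]), logical(1))
  res
}
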