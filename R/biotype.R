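#' Default biotype taxonomy
#'
#' Ordered class names used for biotype attribution.  Endogenous
#' retroelements are grouped by RepeatMasker repeat class (LINE/SINE/LTR,
#' everything else under `ERE_other`); the taxonomy is configurable wherever
#' it is consumed.
#'
#' @return Character vector of class names.
#' @export
default_taxonomy <- function() {
  c("in_frame", "out_of_frame_exon", "UTR5", "UTR3", "non_coding_exon",
    "pseudogene_exon", "intron", "ERE_LINE", "ERE_SINE", "ERE_LTR",
    "ERE_other", "exon_intron_junction", "intergenic")
}

ere_class <- function(repeat_class) {
  up <- toupper(repeat_class)
  ifelse(startsWith(up, "LINE"), "ERE_LINE",
  ifelse(startsWith(up, "SINE"), "ERE_SINE",
  ifelse(startsWith(up, "LTR"), "ERE_LTR", "ERE_other")))
}

#' Frame status of a location within a coding transcript
#'
#' A placement is in frame when all of its blocks lie within the transcript's
#' CDS, its block boundaries are splice-consistent with the transcript (the
#' placement occupies a contiguous run of the spliced coding sequence), its
#' strand equals the transcript strand, and its first base (in coding order)
#' sits at a codon boundary.
#'
#' @param location One location row.
#' @param tx One transcript model from an `AnnotationIndex`.
#' @return `"in_frame"`, `"out_of_frame"`, or `"not_applicable"` (transcript
#'   without CDS, or location not fully inside the CDS).
#' @export
frame_status <- function(location, tx) {
  if (length(tx$cds) == 0L) return("not_applicable")
  if (location$chrom != tx$chrom) return("not_applicable")
  blocks <- location_blocks(location)
  gpos <- unlist(lapply(seq_len(nrow(blocks)),
                        function(i) blocks[i, "start"]:blocks[i, "end"]))
  # genomic positions of the CDS in coding (5'->3') order
  cds_pos <- unlist(lapply(seq_along(tx$cds), function(i)
    IRanges::start(tx$cds)[i]:IRanges::end(tx$cds)[i]))
  if (tx$strand == "-") cds_pos <- rev(cds_pos)
  idx <- match(gpos, cds_pos)
  if (anyNA(idx)) return("not_applicable")
  if (location$strand != tx$strand) return("out_of_frame")
  coding_order <- if (tx$strand == "+") idx else rev(idx)
  if (!all(diff(coding_order) == 1L)) return("out_of_frame")  # splice-inconsistent
  if ((coding_order[1] - 1L) %% 3L == 0L) "in_frame" else "out_of_frame"
}

#' Biotype classes overlapping a location
#'
#' Intersects a location with the annotation index and maps every
#' overlapping feature to a biotype class with its overlap width.  A
#' location overlapping both exonic and intronic parts of one transcript is
#' classed `exon_intron_junction` for that transcript; CDS overlaps are
#' split into `in_frame` / `out_of_frame_exon` by [frame_status()]; a
#' location with no overlap at all is `intergenic` over its full width.
#' Features are matched regardless of strand by default.
#'
#' @param location One location row.
#' @param index An `AnnotationIndex`.
#' @param stranded If `TRUE`, only same-strand features contribute.
#' @return Data frame with `class` and `overlap_bp`, aggregated by class.
#' @export
overlap_biotypes <- function(location, index, stranded = FALSE) {
  blocks <- location_blocks(location)
  feats <- list(); eres <- list()
  for (i in seq_len(nrow(blocks))) {
    q <- query_features(index, location$chrom, blocks[i, "start"], blocks[i, "end"])
    if (nrow(q$features)) feats[[length(feats) + 1L]] <- q$features
    if (nrow(q$ere)) eres[[length(eres) + 1L]] <- q$ere
  }
  feats <- if (length(feats)) do.call(rbind, feats) else data.frame()
  eres <- if (length(eres)) do.call(rbind, eres) else data.frame()
  if (stranded) {
    if (nrow(feats)) feats <- feats[feats$strand == location$strand, , drop = FALSE]
    if (nrow(eres)) eres <- eres[eres$strand == location$strand, , drop = FALSE]
  }
  rows <- list()
  add <- function(class, bp) {
    if (bp > 0L) rows[[length(rows) + 1L]] <<- data.frame(
      class = class, overlap_bp = bp, stringsAsFactors = FALSE)
  }
  if (nrow(feats)) {
    for (txid in unique(feats$transcript_id)) {
      f <- feats[feats$transcript_id == txid, , drop = FALSE]
      exonic <- f$feature %in% c("CDS", "UTR5", "UTR3", "exon")
      if (any(exonic) && any(f$feature == "intron")) {
        add("exon_intron_junction", sum(f$overlap_bp))
        next
      }
      if (all(f$feature == "intron")) {
        add("intron", sum(f$overlap_bp))
        next
      }
      biotype <- f$biotype[1]
      if (any(f$feature == "exon")) {
        cls <- if (grepl("pseudogene", biotype)) "pseudogene_exon" else "non_coding_exon"
        add(cls, sum(f$overlap_bp[f$feature == "exon"]))
      }
      if (any(f$feature == "CDS")) {
        tx <- index$transcripts[[txid]]
        fs <- frame_status(location, tx)
        cls <- if (identical(fs, "in_frame")) "in_frame" else "out_of_frame_exon"
        add(cls, sum(f$overlap_bp[f$feature == "CDS"]))
      }
      add("UTR5", sum(f$overlap_bp[f$feature == "UTR5"]))
      add("UTR3", sum(f$overlap_bp[f$feature == "UTR3"]))
    }
  }
  if (nrow(eres)) {
    ec <- ere_class(eres$repeat_class)
    for (cls in unique(ec)) add(cls, sum(eres$overlap_bp[ec == cls]))
  }
  if (length(rows) == 0L) {
    width <- sum(blocks[, "end"] - blocks[, "start"] + 1L)
    return(data.frame(class = "intergenic", overlap_bp = width,
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  stats::aggregate(overlap_bp ~ class, data = out, FUN = sum)
}

#' Annotate a location table with biotype class sets
#'
#' @param locations Location data.frame (deduplicated by `loc_id`).
#' @param index An `AnnotationIndex`.
#' @param stranded Passed to [overlap_biotypes()].
#' @return `locations` with a list-column `classes` (character vectors) and
#'   `class_overlaps` (named overlap widths).
#' @export
biotype_classify <- function(locations, index, stranded = FALSE) {
  key <- if ("peptide" %in% names(locations))
    paste(locations$peptide, locations$loc_id) else locations$loc_id
  locations <- locations[!duplicated(key), , drop = FALSE]
  ann <- lapply(seq_len(nrow(locations)), function(i)
    overlap_biotypes(locations[i, , drop = FALSE], index, stranded = stranded))
  locations$classes <- lapply(ann, function(a) a$class)
  locations$class_overlaps <- lapply(ann, function(a)
    stats::setNames(a$overlap_bp, a$class))
  locations
}

#' Fit the biotype apportionment by expectation-maximization
#'
#' Multi-mapping peptides spread their reads over locations carrying
#' different biotype class sets; the EM estimates one coefficient per class
#' shared across all queried peptides.  Every class coefficient starts at
#' 0.1.  E-step: each peptide's reads are distributed over classes, each
#' location contributing its read count split proportionally to the current
#' coefficients of the classes present there, normalized by the peptide's
#' total reads.  M-step: the new coefficient of a class is the mean of the
#' per-peptide distributions.  Iteration stops when no coefficient moves by
#' more than `tol` (the printed rule is exact equality of successive
#' coefficient sets; a tolerance makes that robust in floating point).
#'
#' @param loc_tbl Data.frame with columns `peptide`, `loc_id`, `reads`
#'   (summed over the samples in scope) and list-column `classes`.
#' @param tol Convergence tolerance on the max absolute coefficient change.
#' @param max_iter Iteration cap.
#' @return An `EMState`: list with `phi` (named coefficients), `Z`
#'   (peptide x class read-share matrix), `iterations`, `converged`.
#' @export
em_fit <- function(loc_tbl, tol = 1e-8, max_iter = 10000L) {
  stopifnot(all(c("peptide", "loc_id", "reads", "classes") %in% names(loc_tbl)))
  totals <- tapply(loc_tbl$reads, loc_tbl$peptide, sum)
  fit_peps <- names(totals)[totals > 0]
  if (length(fit_peps) == 0L) stop("EM undefined: no reads at any location")
  tbl <- loc_tbl[loc_tbl$peptide %in% fit_peps, , drop = FALSE]
  classes <- sort(unique(unlist(tbl$classes)))
  phi <- stats::setNames(rep(0.1, length(classes)), classes)
  n <- length(fit_peps)
  e_step <- function(phi) {
    Z <- matrix(0, nrow = n, ncol = length(classes),
                dimnames = list(fit_peps, classes))
    for (i in seq_len(nrow(tbl))) {
      cls <- tbl$classes[[i]]
      denom <- sum(phi[cls])
      w <- if (denom > 0) phi[cls] / denom else rep(1 / length(cls), length(cls))
      Z[tbl$peptide[i], cls] <- Z[tbl$peptide[i], cls] +
        tbl$reads[i] * w / totals[[tbl$peptide[i]]]
    }
    Z
  }
  converged <- FALSE
  iter <- 0L
  Z <- NULL
  while (iter < max_iter) {
    iter <- iter + 1L
    Z <- e_step(phi)
    phi_new <- colMeans(Z)
    if (max(abs(phi_new - phi)) < tol) {
      phi <- phi_new
      converged <- TRUE
      break
    }
    phi <- phi_new
  }
  structure(list(phi = phi, Z = Z, iterations = iter, converged = converged,
                 classes = classes),
            class = "EMState")
}

#' Per-location biotype shares after EM
#'
#' The share of class *j* at a location is its converged coefficient
#' normalized by the sum of coefficients of all classes present at the
#' location.
#'
#' @param em An `EMState`.
#' @param classes_at_loc Character vector of classes present at the location.
#' @return Named numeric vector summing to 1.
#' @export
location_shares <- function(em, classes_at_loc) {
  phi <- em$phi[classes_at_loc]
  phi[is.na(phi)] <- 0
  denom <- sum(phi)
  if (denom > 0) {
    stats::setNames(as.numeric(phi) / denom, classes_at_loc)
  } else {
    stats::setNames(rep(1 / length(classes_at_loc), length(classes_at_loc)),
                    classes_at_loc)
  }
}

#' Biotype percentages for one peptide over a read scope
#'
#' Distributes the reads of every location over classes by the post-EM
#' location shares, sums over locations, and normalizes by the peptide's
#' total reads in the scope, yielding percentages.
#'
#' @param em An `EMState`.
#' @param loc_tbl Rows of one peptide: `loc_id`, `reads` (in the scope),
#'   list-column `classes`.
#' @return Named percentage vector summing to 100, or `NULL` when the scope
#'   holds no reads (profile undefined).
#' @export
peptide_biotype_pct <- function(em, loc_tbl) {
  total <- sum(loc_tbl$reads)
  if (total <= 0) return(NULL)
  acc <- stats::setNames(numeric(length(em$classes)), em$classes)
  for (i in seq_len(nrow(loc_tbl))) {
    sh <- location_shares(em, loc_tbl$classes[[i]])
    acc[names(sh)] <- acc[names(sh)] + loc_tbl$reads[i] * sh
  }
  100 * acc / total
}

#' Best-guess biotype
#'
#' A peptide that can arise in frame of a known protein anywhere is called
#' `in_frame` (with its certainty equal to the in-frame percentage);
#' otherwise the highest-percentage class wins, and exact ties are all
#' reported.
#'
#' @param pct Named percentage vector (see [peptide_biotype_pct()]).
#' @param has_in_frame_location Does any location of the peptide carry the
#'   `in_frame` class?
#' @return List with `best` (character vector of one or more classes) and
#'   `certainty` (percentage of the first best class).
#' @export
best_guess <- function(pct, has_in_frame_location) {
  if (has_in_frame_location) {
    cert <- if ("in_frame" %in% names(pct)) unname(pct[["in_frame"]]) else 0
    return(list(best = "in_frame", certainty = cert))
  }
  top <- max(pct)
  best <- names(pct)[abs(pct - top) < 1e-9]
  list(best = best, certainty = unname(top))
}

#' Biotype profiles at the three reporting scopes
#'
#' Computes, for every peptide: (a) per-location class shares, (b) the
#' global profile over all samples, and (c) one profile per sample cohort,
#' plus the best guess from the global profile.
#'
#' @param biotyped_locs Location table from [biotype_classify()], one row per
#'   unique location per peptide (column `peptide` required).
#' @param per_location_counts Long data.frame `peptide`, `loc_id`,
#'   `sample_name`, `count`.
#' @param cohorts Optional named list: cohort name -> character vector of
#'   sample names.
#' @param tol,max_iter Passed to [em_fit()].
#' @return List with `em`, `per_location` (shares), `global` (per-peptide
#'   percentage data.frame), `cohort` (named list of the same), `best`
#'   (per-peptide best-guess data.frame).
#' @export
biotype_profile <- function(biotyped_locs, per_location_counts, cohorts = NULL,
                            tol = 1e-8, max_iter = 10000L) {
  agg <- stats::aggregate(count ~ peptide + loc_id, data = per_location_counts,
                          FUN = sum)
  tbl <- merge(biotyped_locs[, c("peptide", "loc_id")], agg,
               by = c("peptide", "loc_id"), all.x = TRUE)
  tbl$count[is.na(tbl$count)] <- 0L
  m <- match(paste(tbl$peptide, tbl$loc_id),
             paste(biotyped_locs$peptide, biotyped_locs$loc_id))
  tbl$classes <- biotyped_locs$classes[m]
  names(tbl)[names(tbl) == "count"] <- "reads"
  em <- em_fit(tbl, tol = tol, max_iter = max_iter)

  per_loc <- lapply(seq_len(nrow(tbl)), function(i)
    location_shares(em, tbl$classes[[i]]))
  names(per_loc) <- paste(tbl$peptide, tbl$loc_id, sep = "::")

  scope_profiles <- function(scope_tbl) {
    peps <- unique(scope_tbl$peptide)
    rows <- lapply(peps, function(p) {
      pct <- peptide_biotype_pct(em, scope_tbl[scope_tbl$peptide == p, ,
                                               drop = FALSE])
      if (is.null(pct)) return(NULL)
      cbind(data.frame(peptide = p, stringsAsFactors = FALSE),
            as.data.frame(as.list(pct), check.names = FALSE))
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows) == 0L) return(NULL)
    do.call(rbind, rows)
  }
  global <- scope_profiles(tbl)

  cohort_out <- NULL
  if (!is.null(cohorts)) {
    cohort_out <- lapply(cohorts, function(members) {
      sub <- per_location_counts[per_location_counts$sample_name %in% members, ,
                                 drop = FALSE]
      if (nrow(sub) == 0L) stop("Empty cohort scope")
      agg_s <- stats::aggregate(count ~ peptide + loc_id, data = sub, FUN = sum)
      stbl <- merge(tbl[, c("peptide", "loc_id")], agg_s,
                    by = c("peptide", "loc_id"), all.x = TRUE)
      stbl$count[is.na(stbl$count)] <- 0L
      stbl$classes <- tbl$classes[match(paste(stbl$peptide, stbl$loc_id),
                                        paste(tbl$peptide, tbl$loc_id))]
      names(stbl)[names(stbl) == "count"] <- "reads"
      scope_profiles(stbl)
    })
  }

  best <- NULL
  if (!is.null(global)) {
    best <- do.call(rbind, lapply(seq_len(nrow(global)), function(i) {
      p <- global$peptide[i]
      pct <- unlist(global[i, -1, drop = FALSE])
      has_if <- any(vapply(which(tbl$peptide == p), function(k)
        "in_frame" %in% tbl$classes[[k]], logical(1)))
      bg <- best_guess(pct, has_if)
      data.frame(peptide = p, best_guess = paste(bg$best, collapse = ";"),
                 certainty = bg$certainty, stringsAsFactors = FALSE)
    }))
  }

  list(em = em, per_location = per_loc, global = global, cohort = cohort_out,
       best = best)
}
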