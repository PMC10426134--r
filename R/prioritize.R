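#' Define sample groups and their screening roles
#'
#' @param samples Data frame with columns `sample_name`, `group`, `role`;
#'   roles are `tolerance` (thymic/dendritic material that induces central
#'   tolerance), `normal` (normal tissues and lineage cells), `tumor`, or
#'   `translation` (ribosome profiling).
#' @return Validated data.frame of class `SampleGroups`.
#' @export
sample_groups <- function(samples) {
  stopifnot(all(c("sample_name", "group", "role") %in% names(samples)))
  bad <- setdiff(unique(samples$role),
                 c("tolerance", "normal", "tumor", "translation"))
  if (length(bad)) stop("Unknown role(s): ", paste(bad, collapse = ", "))
  empty <- table(samples$group) == 0
  if (any(empty)) stop("Empty group(s)")
  class(samples) <- c("SampleGroups", "data.frame")
  samples
}

#' Build a peptide-by-group expression matrix
#'
#' Group expression is the arithmetic mean of per-sample RPHM values
#' (reported alongside the mean log-RPHM and the per-sample maximum).  A
#' missing (peptide, sample) record is an error, never a silent zero.
#'
#' @param records Per-(peptide, sample) records with `peptide`,
#'   `sample_name`, `rphm`, `log_rphm` (e.g. from [count_samples()]).
#' @param groups A `SampleGroups` data.frame.
#' @return Long data.frame of class `ExpressionMatrix`: `peptide`, `group`,
#'   `role`, `mean_rphm`, `mean_log_rphm`, `max_rphm`.
#' @export
build_matrix <- function(records, groups) {
  groups <- sample_groups(as.data.frame(groups))
  peptides <- unique(records$peptide)
  rows <- list()
  for (g in unique(groups$group)) {
    members <- groups$sample_name[groups$group == g]
    role <- groups$role[groups$group == g][1]
    for (p in peptides) {
      r <- records[records$peptide == p & records$sample_name %in% members, ,
                   drop = FALSE]
      if (nrow(r) != length(members))
        stop("Missing record(s) for peptide '", p, "' in group '", g, "'")
      rows[[length(rows) + 1L]] <- data.frame(
        peptide = p, group = g, role = role,
        mean_rphm = mean(r$rphm), mean_log_rphm = mean(r$log_rphm),
        max_rphm = max(r$rphm), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (any(out$mean_rphm < 0)) stop("Negative expression value")
  if ("no_location" %in% names(records)) {
    nl <- tapply(records$no_location, records$peptide, any)
    attr(out, "no_location") <- names(nl)[nl]
  }
  class(out) <- c("ExpressionMatrix", "data.frame")
  out
}

#' Threshold filter against a group role
#'
#' With `direction = "discard_if_ge"` a peptide is discarded when its
#' expression reaches the threshold in any group of the role.  The default
#' threshold, 8.55 RPHM, is the minimum expression conferring a greater than
#' 5\% probability of generating an MHC-I peptide.
#'
#' @param matrix An `ExpressionMatrix`.
#' @param role Group role the filter applies to.
#' @param threshold RPHM threshold (default 8.55).
#' @param direction Only `"discard_if_ge"` is defined.
#' @param per_sample_max Apply the threshold to the per-sample maximum
#'   instead of the group mean.
#' @param exempt_groups Groups ignored by the filter (e.g. testis for the
#'   cancer-testis exemption).
#' @return List: `retained` (peptides), `discarded` (data.frame with the
#'   offending group), `flagged` (peptides above threshold only in exempt
#'   groups).
#' @export
threshold_filter <- function(matrix, role, threshold = 8.55,
                             direction = "discard_if_ge",
                             per_sample_max = FALSE,
                             exempt_groups = character()) {
  stopifnot(identical(direction, "discard_if_ge"))
  m <- matrix[matrix$role == role, , drop = FALSE]
  if (nrow(m) == 0L) stop("No groups with role '", role, "'")
  val <- if (per_sample_max) m$max_rphm else m$mean_rphm
  hot <- m[val >= threshold, , drop = FALSE]
  hot_nonexempt <- hot[!hot$group %in% exempt_groups, , drop = FALSE]
  discarded <- unique(hot_nonexempt[, c("peptide", "group")])
  flagged <- setdiff(unique(hot$peptide), discarded$peptide)
  retained <- setdiff(unique(m$peptide), discarded$peptide)
  list(retained = retained, discarded = discarded, flagged = flagged)
}

#' Tumor-specific-antigen filter cascade
#'
#' Ordered screening of candidate peptides:
#' \enumerate{
#'   \item drop peptides with no genomic location;
#'   \item tolerance filter: discard peptides expressed at or above the
#'     threshold in any tolerance group (mTEC/DC union);
#'   \item normal filter: same rule over normal-tissue groups, with an
#'     optional testis exemption that instead flags survivors as
#'     cancer-testis antigens (CTA);
#'   \item fold change: mean tumor RPHM over mean normal RPHM (pseudocount
#'     0.5 added to the denominator) must reach `fold`;
#'   \item translation evidence: when ribosome-profiling counts are supplied,
#'     candidates need at least one elongation read.
#' }
#' Each discarded peptide records exactly the first stage that removed it.
#'
#' @param matrix An `ExpressionMatrix` covering tolerance, normal and tumor
#'   roles.
#' @param ribo Optional data.frame `peptide`, `ribo_reads`.
#' @param threshold RPHM threshold for stages 2-3 (default 8.55).
#' @param fold Minimum tumor/normal fold change (default 5).
#' @param pseudocount Added to the normal-mean denominator (default 0.5).
#' @param cta_exempt_groups Normal-role groups covered by the CTA exemption.
#' @param per_sample_max See [threshold_filter()].
#' @return Data.frame of `TSACall`s: `peptide`, `tsa`, `cta`,
#'   `discarded_at`, `fold_change`, `ribo_reads`.
#' @export
tsa_cascade <- function(matrix, ribo = NULL, threshold = 8.55, fold = 5,
                        pseudocount = 0.5, cta_exempt_groups = character(),
                        per_sample_max = FALSE) {
  for (role in c("tolerance", "normal", "tumor"))
    if (!any(matrix$role == role)) stop("Missing mandatory role: ", role)
  peptides <- sort(unique(matrix$peptide))
  call <- data.frame(peptide = peptides, tsa = FALSE, cta = FALSE,
                     discarded_at = NA_character_, fold_change = NA_real_,
                     ribo_reads = NA_real_, stringsAsFactors = FALSE)
  live <- peptides

  no_loc <- attr(matrix, "no_location")
  if (!is.null(no_loc) && length(no_loc)) {
    call$discarded_at[call$peptide %in% no_loc] <- "no_location"
    live <- setdiff(live, no_loc)
  }

  tol <- threshold_filter(matrix, "tolerance", threshold,
                          per_sample_max = per_sample_max)
  drop <- intersect(live, tol$discarded$peptide)
  call$discarded_at[call$peptide %in% drop] <- "tolerance"
  live <- setdiff(live, drop)

  nrm <- threshold_filter(matrix, "normal", threshold,
                          per_sample_max = per_sample_max,
                          exempt_groups = cta_exempt_groups)
  drop <- intersect(live, nrm$discarded$peptide)
  call$discarded_at[call$peptide %in% drop] <- "normal"
  live <- setdiff(live, drop)
  call$cta[call$peptide %in% intersect(live, nrm$flagged)] <- TRUE

  tumor_mean <- tapply(matrix$mean_rphm[matrix$role == "tumor"],
                       matrix$peptide[matrix$role == "tumor"], mean)
  # exempt (testis) groups stay out of the normal baseline, or no
  # cancer-testis candidate could ever clear the fold-change stage
  nrm_rows <- matrix$role == "normal" & !matrix$group %in% cta_exempt_groups
  normal_mean <- tapply(matrix$mean_rphm[nrm_rows],
                        matrix$peptide[nrm_rows], mean)
  fc <- tumor_mean[live] / (normal_mean[live] + pseudocount)
  call$fold_change[match(live, call$peptide)] <- fc
  drop <- live[fc < fold]
  call$discarded_at[call$peptide %in% drop] <- "fold_change"
  live <- setdiff(live, drop)

  if (!is.null(ribo)) {
    rr <- ribo$ribo_reads[match(live, ribo$peptide)]
    rr[is.na(rr)] <- 0
    call$ribo_reads[match(live, call$peptide)] <- rr
    drop <- live[rr <= 0]
    call$discarded_at[call$peptide %in% drop] <- "translation"
    live <- setdiff(live, drop)
  }

  call$tsa[call$peptide %in% live] <- TRUE
  call$cta[!call$tsa] <- FALSE
  call
}

#' Fit the expression-based immunogenicity model
#'
#' L2-regularized logistic regression on two tolerance-compartment
#' expression features (mean RPHM in mTEC and in dendritic cells);
#' immunogenic peptides tend to be the lower-expressed ones.
#'
#' @param features Numeric matrix/data.frame (peptides x 2 features).
#' @param labels Logical or two-level factor: immunogenic yes/no.
#' @param lambda Ridge penalty (default `1/nrow(features)`, the counterpart
#'   of the scikit-learn default `C = 1`).
#' @return An `ImmunoModel`.
#' @export
fit_immunogenicity <- function(features, labels, lambda = NULL) {
  x <- as.matrix(features)
  y <- as.integer(as.logical(labels))
  if (length(unique(y)) < 2L) stop("Both immunogenic and non-immunogenic labels required")
  if (is.null(lambda)) lambda <- 1 / nrow(x)
  fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                        lambda = lambda, standardize = FALSE)
  structure(list(fit = fit, lambda = lambda, features = colnames(x)),
            class = "ImmunoModel")
}

#' Predict immunogenicity probabilities
#'
#' @param model An `ImmunoModel`.
#' @param features Numeric matrix/data.frame with the training columns.
#' @return Numeric vector of probabilities.
#' @export
predict_immunogenicity <- function(model, features) {
  as.numeric(stats::predict(model$fit, newx = as.matrix(features),
                            type = "response"))
}

#' Cross-validated AUC of the immunogenicity model
#'
#' Stratified random splits (default 10 repeats, 20\% held out per repeat);
#' reports the mean ROC-AUC over repeats.
#'
#' @inheritParams fit_immunogenicity
#' @param n_splits Number of random splits.
#' @param test_size Held-out fraction per split.
#' @param seed RNG seed for the splits.
#' @return List with `mean_auc` and per-split `auc`.
#' @export
cv_immunogenicity <- function(features, labels, n_splits = 10L,
                              test_size = 0.2, seed = 1L) {
  x <- as.matrix(features)
  y <- as.logical(labels)
  if (length(unique(y)) < 2L) stop("Both classes required")
  idx_pos <- which(y); idx_neg <- which(!y)
  n_test_pos <- max(1L, round(length(idx_pos) * test_size))
  n_test_neg <- max(1L, round(length(idx_neg) * test_size))
  set.seed(seed)
  aucs <- vapply(seq_len(n_splits), function(s) {
    test <- c(sample(idx_pos, n_test_pos), sample(idx_neg, n_test_neg))
    train <- setdiff(seq_along(y), test)
    model <- fit_immunogenicity(x[train, , drop = FALSE], y[train])
    p <- predict_immunogenicity(model, x[test, , drop = FALSE])
    as.numeric(pROC::auc(pROC::roc(response = y[test], predictor = p,
                                   quiet = TRUE, direction = "<",
                                   levels = c(FALSE, TRUE))))
  }, numeric(1))
  list(mean_auc = mean(aucs), auc = aucs)
}
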