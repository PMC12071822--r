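#' Encode baseline clinical features as a numeric vector
#'
#' Transforms the four baseline clinical variables into the
#' one-dimensional numeric vector used by the fusion classifier:
#' `[age, log10(PSA + 1), Gleason, TNM ordinal]`. PSA is log-transformed
#' because it spans orders of magnitude (set `log_psa = FALSE` for the
#' raw value). The clinical TNM stage code is mapped to the ordinal
#' `T + 0.25 * [N >= 1] + 0.5 * [M >= 1]`, which is strictly monotone in
#' each component and invertible over the documented code list
#' (T1..T4 x N0/N1 x M0/M1; N2/N3 encode as nodal presence). Missing
#' fields are an error — no silent imputation.
#'
#' @param record a list or one-row data frame with `age`, `psa`,
#'   `gleason`, `tnm`; or a multi-row data frame (returns a matrix).
#' @param log_psa log-transform PSA (default `TRUE`).
#' @return Numeric vector of length 4, or an n x 4 matrix for a data
#'   frame with n rows.
#' @export
encode_clinical <- function(record, log_psa = TRUE) {
  need <- c("age", "psa", "gleason", "tnm")
  if (is.data.frame(record) && nrow(record) > 1) {
    out <- t(vapply(seq_len(nrow(record)),
                    function(i) encode_clinical(record[i, ], log_psa),
                    numeric(4)))
    rownames(out) <- record$patient_id
    return(out)
  }
  record <- as.list(record)
  miss <- setdiff(need, names(record))
  bad <- need[vapply(need, function(f) is.null(record[[f]]) ||
                       is.na(record[[f]]), logical(1))]
  if (length(miss) || length(bad))
    stop("missing clinical field(s): ", paste(union(miss, bad), collapse = ", "))
  if (record$psa < 0) stop("psa must be non-negative")
  if (!(record$gleason %in% 6:10)) stop("gleason must be in 6..10")
  c(age = as.numeric(record$age),
    psa = if (log_psa) log10(record$psa + 1) else as.numeric(record$psa),
    gleason = as.numeric(record$gleason),
    tnm = tnm_ordinal(record$tnm))
}

#' @rdname encode_clinical
#' @param tnm clinical stage code such as `"T2N0M0"` or `"T3aN1M0"`.
#' @export
tnm_ordinal <- function(tnm) {
  m <- regmatches(tnm, regexec("^T([1-4])[a-c]?N([0-3])M([0-1])$",
                               toupper(tnm)))[[1]]
  if (length(m) != 4) stop("unparseable TNM code: ", tnm)
  v <- as.integer(m[2:4])
  v[1] + 0.25 * (v[2] >= 1) + 0.5 * (v[3] >= 1)
}

#' @rdname encode_clinical
#' @param x an ordinal produced by [tnm_ordinal()].
#' @export
tnm_from_ordinal <- function(x) {
  t_digit <- floor(x + 1e-9)
  frac <- round((x - t_digit) * 4)
  sprintf("T%dN%dM%d", t_digit, frac %% 2, frac %/% 2)
}

#' Concatenate image and clinical feature vectors
#'
#' Fuses the two modality vectors by concatenation, image features first.
#' Non-finite inputs are rejected.
#'
#' @param image_vec numeric image feature vector.
#' @param clinical_vec numeric clinical feature vector.
#' @return Numeric vector of length `length(image_vec) +
#'   length(clinical_vec)`.
#' @export
fuse_features <- function(image_vec, clinical_vec) {
  if (any(!is.finite(image_vec)) || any(!is.finite(clinical_vec)))
    stop("feature vectors must be finite")
  c(image_vec, clinical_vec)
}

# fused design matrix for a set of samples
fusion_matrix <- function(net, samples, clinical_table, feature_mode) {
  x <- sample_batch(samples, net)
  fw <- forward_net(net, x, training = FALSE)
  img <- if (feature_mode == "scores") fw$scores else fw$spp
  clin <- encode_clinical(clinical_table)
  pid <- vapply(samples, function(s) s$patient_id, character(1))
  rows <- match(pid, clinical_table$patient_id)
  if (anyNA(rows)) stop("samples reference patients absent from the clinical table")
  cbind(t(img), clin[rows, , drop = FALSE])
}

#' Train the two-stage fusion model
#'
#' Stage 2 of the multimodal model: the per-sample image feature vector
#' from the trained stage-1 network (the fully connected head's class
#' scores by default, or the richer pre-head SPP vector) is concatenated
#' with the encoded clinical vector, and a gradient-boosted tree
#' classifier (XGBoost, binary logistic) is fitted on the training-set
#' fused vectors with early stopping monitored on the validation set. The
#' split must be identical to the one the image model was trained on —
#' a mismatch is an error — and the test set is never touched.
#'
#' @param stage1_model a [train()]ed network.
#' @param samples list of samples (the full cohort's slices).
#' @param clinical_table data frame with `patient_id`, `age`, `psa`,
#'   `gleason`, `tnm`, `label`.
#' @param split_plan the [make_splits()] plan used for stage 1.
#' @param round split round; must equal the stage-1 round.
#' @param boost_params list with `max_depth`, `eta`, `nrounds`,
#'   `early_stopping_rounds`.
#' @param feature_mode `"scores"` (default) or `"spp"`.
#' @param seed integer seed for the booster.
#' @return An object of class `fusion_model`.
#' @export
train_fusion <- function(stage1_model, samples, clinical_table, split_plan,
                         round = 1, boost_params = list(),
                         feature_mode = c("scores", "spp"), seed = 1) {
  feature_mode <- match.arg(feature_mode)
  stopifnot(inherits(stage1_model, "sspp_net"))
  if (!isTRUE(stage1_model$trained)) stop("stage-1 model is untrained")
  rd <- split_plan$rounds[[round]]
  si <- stage1_model$split_info
  if (is.null(si) || si$round != round ||
      !identical(si$train, sort(rd$train)) ||
      !identical(si$test, sort(rd$test)))
    stop("stage-2 split does not match the stage-1 training split")
  bp <- utils::modifyList(list(max_depth = 3, eta = 0.1, nrounds = 200,
                               early_stopping_rounds = 20), boost_params)
  pid <- vapply(samples, function(s) s$patient_id, character(1))
  lab <- vapply(samples, function(s) as.integer(s$label), integer(1))
  tr <- which(pid %in% rd$train); va <- which(pid %in% rd$validation)
  xtr <- fusion_matrix(stage1_model, samples[tr], clinical_table, feature_mode)
  xva <- fusion_matrix(stage1_model, samples[va], clinical_table, feature_mode)
  dtr <- xgboost::xgb.DMatrix(xtr, label = lab[tr])
  dva <- xgboost::xgb.DMatrix(xva, label = lab[va])
  booster <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = bp$max_depth,
                  eta = bp$eta, eval_metric = "logloss", nthread = 1,
                  seed = seed),
    data = dtr, nrounds = bp$nrounds,
    evals = list(validation = dva),
    early_stopping_rounds = bp$early_stopping_rounds, verbose = 0)
  structure(list(net = stage1_model, booster = booster,
                 feature_mode = feature_mode, round = round,
                 split = rd, seed = seed,
                 clinical_cols = colnames(xtr)),
            class = "fusion_model")
}

#' Predict progression with a fusion model
#'
#' Computes the fused feature vector for each sample and returns the
#' boosted classifier's progression probability (class 1) and the 0.5-
#' threshold label. Per-slice predictions can be aggregated to patient
#' level with [aggregate_patient()].
#'
#' @param fusion a [train_fusion()] model.
#' @param samples list of samples.
#' @param clinical_table the clinical data frame.
#' @return data frame with `patient_id`, `slice_index`, `prob`, `label`.
#' @export
predict_fusion <- function(fusion, samples, clinical_table) {
  x <- fusion_matrix(fusion$net, samples, clinical_table, fusion$feature_mode)
  prob <- stats::predict(fusion$booster, xgboost::xgb.DMatrix(x))
  data.frame(
    patient_id = vapply(samples, function(s) s$patient_id, character(1)),
    slice_index = vapply(samples, function(s) as.integer(s$slice_index),
                         integer(1)),
    prob = as.numeric(prob), label = as.integer(prob > 0.5))
}

#' Aggregate slice-level probabilities to patient level
#'
#' Mean slice probability per patient, thresholded at 0.5.
#'
#' @param prob numeric slice probabilities.
#' @param patient_id patient id per slice.
#' @return data frame with `patient_id`, `prob`, `label`.
#' @export
aggregate_patient <- function(prob, patient_id) {
  agg <- tapply(prob, patient_id, mean)
  data.frame(patient_id = names(agg), prob = as.numeric(agg),
             label = as.integer(agg > 0.5), row.names = NULL)
}
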