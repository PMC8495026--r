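# Two-layer stacked sex classifier. First layer: one k-NN per
# (lead, plane, measure-set) feature block, emitting the posterior
# probability of female. Second layer: a shallow feed-forward network (one
# hidden layer, logistic activations) stacked on the posteriors, at lead
# level (60 inputs: 20 planes x 3 measure sets) and at subject level
# (720 inputs: 12 leads x 60). Validation folds are kept independent of
# test folds by nesting the cross-validation, and a provenance log records
# every record's role in every run so leakage can be audited.

#' Sex/age-stratified fold assignment
#'
#' Records are grouped into strata by sex crossed with 10-year age band
#' (missing age is its own stratum). Within each stratum the records are
#' shuffled (seeded) and dealt round-robin; stratum remainders go to the
#' globally least-loaded folds, so fold sizes differ by at most one both
#' overall and within every stratum.
#'
#' @param meta data.frame with columns `record_id`, `sex` and `age` (an
#'   `ecg_cohort` is also accepted).
#' @param n_folds Number of folds (default 10).
#' @param seed Integer seed; the assignment is deterministic given it.
#' @return A `fold_assignment`: list with `assignment` (data.frame
#'   record_id / fold / stratum), `n_folds`, `seed`, `fold_sizes`.
#' @export
stratified_folds <- function(meta, n_folds = 10, seed = 1L) {
  if (inherits(meta, "ecg_cohort")) meta <- cohort_metadata(meta)
  stopifnot(all(c("record_id", "sex", "age") %in% colnames(meta)))
  n <- nrow(meta)
  if (n_folds > n) stop("n_folds (", n_folds, ") exceeds record count (", n, ")")
  decade <- ifelse(is.na(meta$age), "NA", as.character(meta$age %/% 10 * 10))
  stratum <- paste(meta$sex, decade, sep = "/")
  fold <- integer(n)
  totals <- numeric(n_folds)
  with_seed(seed, {
    for (s in sort(unique(stratum))) {
      idx <- which(stratum == s)
      idx <- idx[sample.int(length(idx))]
      m <- length(idx)
      q <- m %/% n_folds; r <- m %% n_folds
      assign_folds <- integer(0)
      if (q > 0) assign_folds <- rep(seq_len(n_folds), q)
      rem_folds <- integer(0)
      if (r > 0) {
        order_pref <- sample.int(n_folds)  # seeded tie-break
        avail <- seq_len(n_folds)
        for (j in seq_len(r)) {
          load <- totals[avail]
          cand <- avail[load == min(load)]
          pick <- cand[which.min(match(cand, order_pref))]
          rem_folds <- c(rem_folds, pick)
          avail <- setdiff(avail, pick)
        }
        assign_folds <- c(assign_folds, rem_folds)
      }
      fold[idx] <- assign_folds
      totals <- totals + tabulate(assign_folds, nbins = n_folds)
    }
  })
  structure(list(
    assignment = data.frame(record_id = meta$record_id, fold = fold,
                            stratum = stratum, stringsAsFactors = FALSE),
    n_folds = as.integer(n_folds), seed = as.integer(seed),
    fold_sizes = tabulate(fold, nbins = n_folds)
  ), class = "fold_assignment")
}

#' @export
print.fold_assignment <- function(x, ...) {
  cat(sprintf("<fold_assignment> %d records in %d folds (sizes %s)\n",
              nrow(x$assignment), x$n_folds,
              paste(x$fold_sizes, collapse = "/")))
  invisible(x)
}

#' k-NN posterior probability of female
#'
#' The posterior is the unweighted fraction of the `k` nearest training
#' vectors (Euclidean distance) labelled female; distance ties are broken by
#' the lower training-record index.
#'
#' @param train_x Training feature matrix (rows = records).
#' @param train_female Logical vector, `TRUE` for female training records.
#' @param query_x Query feature matrix (or vector).
#' @param k Neighbour count, `1 <= k <= nrow(train_x)`.
#' @return Numeric vector of posterior probabilities in `[0, 1]`, one per
#'   query row.
#' @export
knn_posterior <- function(train_x, train_female, query_x, k = 20) {
  train_x <- as.matrix(train_x)
  if (is.null(dim(query_x))) query_x <- matrix(query_x, nrow = 1)
  query_x <- as.matrix(query_x)
  n_train <- nrow(train_x)
  if (n_train == 0) stop("empty training set")
  if (k < 1 || k > n_train)
    stop("k must be in 1..", n_train, ", got ", k)
  if (ncol(train_x) != ncol(query_x))
    stop("feature length mismatch: ", ncol(train_x), " vs ", ncol(query_x))
  train_female <- as.logical(train_female)
  # squared Euclidean distances, queries x train
  d2 <- outer(rowSums(query_x^2), rowSums(train_x^2), "+") -
    2 * query_x %*% t(train_x)
  apply(d2, 1, function(row) {
    nb <- order(row, seq_along(row))[seq_len(k)]  # ties -> lower index
    mean(train_female[nb])
  })
}

#' Canonical posterior-block column keys
#'
#' Fixed feature ordering for the stacker input: lead (standard 12-lead
#' order), then N ascending, then k ascending, then measure kind
#' (r density, theta density, outline r).
#'
#' @param leads Lead labels.
#' @param planes List of projection planes.
#' @return Character vector of `lead|Nx|ky|kind` keys.
#' @export
posterior_keys <- function(leads, planes = enumerate_planes()) {
  leads <- STANDARD_LEADS[STANDARD_LEADS %in% leads]
  keys <- character(0)
  for (lead in leads)
    for (pl in planes)
      for (kind in MEASURE_KINDS)
        keys <- c(keys, sprintf("%s|N%d|k%d|%s", lead, pl$N, pl$k, kind))
  keys
}

#' Assemble stacker feature vectors from a posterior block
#'
#' @param posteriors Matrix of first-layer posteriors, columns named with
#'   the canonical `lead|N|k|kind` keys.
#' @param level `"subject"` (all leads; 720 columns for 12 leads x 20 planes
#'   x 3 kinds) or `"lead"` (one lead; 60 columns).
#' @param lead Lead label, required when `level = "lead"`.
#' @param leads,planes Expected composition, used to verify completeness.
#' @return Matrix of stacker features in canonical column order.
#' @export
build_stack_features <- function(posteriors, level = c("subject", "lead"),
                                 lead = NULL, leads = STANDARD_LEADS,
                                 planes = enumerate_planes()) {
  level <- match.arg(level)
  want <- if (level == "lead") {
    if (is.null(lead)) stop("lead required at lead level")
    posterior_keys(lead, planes)
  } else {
    posterior_keys(leads, planes)
  }
  missing <- setdiff(want, colnames(posteriors))
  if (length(missing))
    stop("missing posterior entr", if (length(missing) > 1) "ies: " else "y: ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) " ..." else "")
  out <- posteriors[, want, drop = FALSE]
  if (any(out < 0 | out > 1)) stop("posterior outside [0, 1]")
  out
}

# forward pass of the one-hidden-layer logistic network
mlp_forward <- function(w, x) {
  h <- plogis(cbind(1, x) %*% w$W1)        # n x size
  as.numeric(plogis(cbind(1, h) %*% w$W2)) # n
}

mlp_logloss <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(ifelse(y, log(p), log(1 - p)))
}

#' Train the second-layer neural-network stacker
#'
#' A feed-forward network with one hidden layer (logistic activations,
#' single sigmoid output) is fit on the posterior features by full-batch
#' Adam on the cross-entropy loss with L2 weight decay. A held-out
#' validation portion (seeded stratified split) drives early stopping: the
#' weights with the best validation log-loss are kept, and training halts
#' when the validation loss has not improved for `patience` epochs.
#' Deterministic given `seed`.
#'
#' @param features Numeric matrix of stacker inputs (rows = records).
#' @param female Logical vector, `TRUE` for female.
#' @param seed Integer seed.
#' @param size Hidden units (default 25).
#' @param decay L2 weight-decay coefficient.
#' @param val_frac Fraction held out for validation (default 0.2).
#' @param max_epochs Epoch cap.
#' @param patience Early-stopping patience in epochs.
#' @param learning_rate Adam step size.
#' @return A `spar_stacker` with the weight matrices and the training trace.
#' @export
train_stacker <- function(features, female, seed = 1L, size = 25,
                          decay = 1e-3, val_frac = 0.2, max_epochs = 500,
                          patience = 50, learning_rate = 0.05) {
  x <- as.matrix(features)
  y <- as.logical(female)
  if (length(unique(y)) < 2)
    stop("stacker training requires both classes")
  if (sum(y) < 2 || sum(!y) < 2)
    stop("need at least 2 records per class")
  n <- nrow(x)
  with_seed(seed, {
    val <- logical(n)
    for (cls in c(TRUE, FALSE)) {
      idx <- which(y == cls)
      n_val <- max(1L, round(length(idx) * val_frac))
      val[sample(idx, n_val)] <- TRUE
    }
    if (all(val) || !any(val)) stop("degenerate validation split")
    xt <- x[!val, , drop = FALSE]; yt <- y[!val]
    xv <- x[val, , drop = FALSE]; yv <- y[val]
    p_in <- ncol(x)
    w <- list(W1 = matrix(stats::rnorm((p_in + 1) * size, sd = 0.3), p_in + 1, size),
              W2 = matrix(stats::rnorm(size + 1, sd = 0.3), size + 1, 1))
    m <- lapply(w, function(z) z * 0); v <- lapply(w, function(z) z * 0)
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    best <- list(w = w, loss = Inf, epoch = 0L)
    trace <- numeric(0)
    xt1 <- cbind(1, xt)
    for (epoch in seq_len(max_epochs)) {
      h <- plogis(xt1 %*% w$W1)
      h1 <- cbind(1, h)
      p <- as.numeric(plogis(h1 %*% w$W2))
      err <- p - yt                                   # dL/dz_out per row
      g2 <- crossprod(h1, err) / nrow(xt) + decay * w$W2
      dh <- (err %*% t(w$W2[-1, , drop = FALSE])) * h * (1 - h)
      g1 <- crossprod(xt1, dh) / nrow(xt) + decay * w$W1
      g <- list(W1 = g1, W2 = g2)
      for (nm in names(w)) {
        m[[nm]] <- b1 * m[[nm]] + (1 - b1) * g[[nm]]
        v[[nm]] <- b2 * v[[nm]] + (1 - b2) * g[[nm]]^2
        mh <- m[[nm]] / (1 - b1^epoch)
        vh <- v[[nm]] / (1 - b2^epoch)
        w[[nm]] <- w[[nm]] - learning_rate * mh / (sqrt(vh) + eps)
      }
      vl <- mlp_logloss(mlp_forward(w, xv), yv)
      trace <- c(trace, vl)
      if (vl < best$loss - 1e-9) best <- list(w = w, loss = vl, epoch = epoch)
      if (epoch - best$epoch >= patience) break
    }
    structure(list(weights = best$w, val_logloss = best$loss,
                   stopped_epoch = best$epoch, trace = trace,
                   size = size, decay = decay, seed = as.integer(seed),
                   feature_names = colnames(x)),
              class = "spar_stacker")
  })
}

#' Score records with a trained stacker
#'
#' @param stacker A `spar_stacker`.
#' @param features Matrix of stacker inputs.
#' @return Numeric scores in `[0, 1]`, female-positive.
#' @export
predict_stacker <- function(stacker, features) {
  features <- as.matrix(features)
  if (!is.null(stacker$feature_names) && !is.null(colnames(features)))
    features <- features[, stacker$feature_names, drop = FALSE]
  mlp_forward(stacker$weights, features)
}

#' Confidence category of a classification score
#'
#' Categories: strong male (< 0.1), mid male (0.1 to < 0.35), indeterminate
#' (0.35 to 0.65), mid female (> 0.65 to 0.9), strong female (> 0.9).
#' Boundary values are assigned to the less extreme category.
#'
#' @param score Numeric score(s) in `[0, 1]`, female-positive.
#' @return Factor with levels strong male, mid male, indeterminate,
#'   mid female, strong female.
#' @export
categorize_score <- function(score) {
  if (any(score < 0 | score > 1 | is.na(score)))
    stop("scores must lie in [0, 1]")
  lev <- c("strong male", "mid male", "indeterminate", "mid female",
           "strong female")
  out <- ifelse(score < 0.1, lev[1],
         ifelse(score < 0.35, lev[2],
         ifelse(score <= 0.65, lev[3],
         ifelse(score <= 0.9, lev[4], lev[5]))))
  factor(out, levels = lev)
}

# ---------------------------------------------------------------------------

fold_indices <- function(folds, meta) {
  fa <- folds$assignment
  match_idx <- match(meta$record_id, fa$record_id)
  if (anyNA(match_idx)) stop("fold assignment missing record(s)")
  fa$fold[match_idx]
}

# first-layer posteriors for the rows `query_idx`, trained on `train_idx`,
# for every feature block; returns matrix rows = queries, cols = keys
block_posteriors <- function(features, train_idx, query_idx, female, k) {
  keys <- features$keys$key
  out <- matrix(NA_real_, nrow = length(query_idx), ncol = length(keys),
                dimnames = list(features$meta$record_id[query_idx], keys))
  for (key in keys) {
    m <- features$features[[key]]
    out[, key] <- knn_posterior(m[train_idx, , drop = FALSE],
                                female[train_idx],
                                m[query_idx, , drop = FALSE], k = k)
  }
  out
}

#' Nested cross-validated stacked classification
#'
#' For each outer test fold, one of the remaining folds is held out as the
#' inner validation fold; the per-block k-NNs are trained on the rest, their
#' out-of-fold posteriors on the validation fold train the subject-level and
#' per-lead stackers, and scores are emitted only for the untouched test
#' fold. A provenance log records every record's role in every run.
#'
#' @param features A `spar_features` object (labels in `features$meta`).
#' @param folds A `fold_assignment` (>= 3 folds).
#' @param k First-layer neighbour count (default 20).
#' @param stack_size Hidden units of the stacker (default 25).
#' @param seed Integer seed for the stacker fits.
#' @param lead_level Also fit per-lead stackers and score each lead
#'   (default `TRUE`).
#' @return A `spar_cv` list: `scores` (data.frame record_id / score / label /
#'   category / fold / sex / age), `lead_scores` (records x leads matrix or
#'   `NULL`), `report` (subject-level [evaluate_scores()]), `lead_reports`,
#'   `provenance` (data.frame run / record_id / role).
#' @export
nested_cross_validate <- function(features, folds, k = 20, stack_size = 25,
                                  seed = 1L, lead_level = TRUE) {
  stopifnot(inherits(features, "spar_features"),
            inherits(folds, "fold_assignment"))
  if (folds$n_folds < 3) stop("nested cross-validation needs >= 3 folds")
  meta <- features$meta
  if (any(!meta$sex %in% c("female", "male")))
    stop("all records must carry a female/male label for classification")
  female <- meta$sex == "female"
  fold_of <- fold_indices(folds, meta)
  planes_df <- unique(features$keys[, c("N", "k")])
  planes <- lapply(seq_len(nrow(planes_df)), function(i)
    projection_plane(planes_df$N[i], planes_df$k[i]))
  n <- nrow(meta)
  scores <- rep(NA_real_, n)
  lead_scores <- if (lead_level)
    matrix(NA_real_, n, length(features$leads),
           dimnames = list(meta$record_id, features$leads)) else NULL
  prov <- list()
  for (o in seq_len(folds$n_folds)) {
    v <- o %% folds$n_folds + 1L
    test_idx <- which(fold_of == o)
    val_idx <- which(fold_of == v)
    train_idx <- which(!fold_of %in% c(o, v))
    if (length(unique(female[train_idx])) < 2 ||
        length(unique(female[val_idx])) < 2)
      stop("fold with a single class encountered in run ", o)
    post <- block_posteriors(features, train_idx, c(val_idx, test_idx),
                             female, k)
    is_val <- seq_along(c(val_idx, test_idx)) <= length(val_idx)
    subj_feat <- build_stack_features(post, "subject",
                                      leads = features$leads,
                                      planes = planes)
    stacker <- train_stacker(subj_feat[is_val, , drop = FALSE],
                             female[val_idx],
                             seed = seed + o, size = stack_size)
    scores[test_idx] <- predict_stacker(stacker,
                                        subj_feat[!is_val, , drop = FALSE])
    if (lead_level) {
      for (lead in features$leads) {
        lf <- build_stack_features(post, "lead", lead = lead,
                                   planes = planes)
        lst <- train_stacker(lf[is_val, , drop = FALSE], female[val_idx],
                             seed = seed + o, size = stack_size)
        lead_scores[test_idx, lead] <-
          predict_stacker(lst, lf[!is_val, , drop = FALSE])
      }
    }
    prov[[o]] <- data.frame(
      run = o,
      record_id = meta$record_id[c(train_idx, val_idx, test_idx)],
      role = rep(c("base_train", "validation", "test"),
                 c(length(train_idx), length(val_idx), length(test_idx))),
      stringsAsFactors = FALSE)
  }
  provenance <- do.call(rbind, prov)
  score_df <- data.frame(
    record_id = meta$record_id, score = scores,
    label = ifelse(scores > 0.5, "female", "male"),
    category = categorize_score(scores),
    fold = fold_of, sex = meta$sex, age = meta$age,
    stringsAsFactors = FALSE)
  report <- evaluate_scores(scores, female, meta$age)
  lead_reports <- NULL
  if (lead_level) {
    lead_reports <- lapply(features$leads, function(lead)
      evaluate_scores(lead_scores[, lead], female, meta$age))
    names(lead_reports) <- features$leads
  }
  structure(list(scores = score_df, lead_scores = lead_scores,
                 report = report, lead_reports = lead_reports,
                 provenance = provenance, k = k, seed = seed),
            class = "spar_cv")
}

#' @export
print.spar_cv <- function(x, ...) {
  cat(sprintf("<spar_cv> %d records, accuracy %.1f%%, AUC %.3f\n",
              nrow(x$scores), x$report$accuracy, x$report$auc))
  invisible(x)
}

#' Audit the provenance log for test-set leakage
#'
#' @param provenance data.frame with columns `run`, `record_id`, `role` (as
#'   produced by [nested_cross_validate()]), or a `spar_cv` object.
#' @return List with `clean` (logical) and `violations` (data.frame of any
#'   test-fold records that also appear in a training role of the same run).
#' @export
audit_leakage <- function(provenance) {
  if (inherits(provenance, "spar_cv")) provenance <- provenance$provenance
  viol <- list()
  for (r in unique(provenance$run)) {
    sub <- provenance[provenance$run == r, ]
    test_ids <- sub$record_id[sub$role == "test"]
    train_ids <- sub$record_id[sub$role %in% c("base_train", "validation")]
    bad <- intersect(test_ids, train_ids)
    if (length(bad))
      viol[[length(viol) + 1]] <- data.frame(run = r, record_id = bad)
  }
  violations <- if (length(viol)) do.call(rbind, viol)
                else data.frame(run = integer(0), record_id = character(0))
  list(clean = nrow(violations) == 0, violations = violations)
}

#' Evaluate classification scores
#'
#' @param scores Numeric scores in `[0, 1]`, female-positive (`NA` allowed,
#'   dropped with their labels).
#' @param female Logical truth, `TRUE` = female.
#' @param age Optional ages for the by-age breakdown.
#' @return An `eval_report`: accuracy (%), `auc` (trapezoidal ROC),
#'   sensitivity/specificity (%, female-positive, `NA` when a class is
#'   absent), `confusion` counts, `by_age` (accuracy per sex x decade),
#'   `by_category` (accuracy and prevalence per confidence category).
#' @export
evaluate_scores <- function(scores, female, age = NULL) {
  keep <- !is.na(scores)
  if (!any(keep)) stop("no scores to evaluate")
  scores <- scores[keep]; female <- as.logical(female)[keep]
  if (!is.null(age)) age <- age[keep]
  pred_female <- scores > 0.5
  tp <- sum(pred_female & female); fn <- sum(!pred_female & female)
  fp <- sum(pred_female & !female); tn <- sum(!pred_female & !female)
  acc <- 100 * (tp + tn) / length(scores)
  sens <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
  auc <- roc_auc(scores, female)
  by_age <- NULL
  if (!is.null(age) && any(!is.na(age))) {
    decade <- ifelse(is.na(age), NA, pmin(age %/% 10 * 10, 90))
    grp <- interaction(ifelse(female, "female", "male"), decade, drop = TRUE)
    by_age <- do.call(rbind, lapply(levels(grp), function(g) {
      i <- grp == g & !is.na(grp)
      data.frame(group = g, n = sum(i),
                 accuracy = 100 * mean(pred_female[i] == female[i]))
    }))
  }
  cats <- categorize_score(scores)
  by_category <- do.call(rbind, lapply(levels(cats), function(cg) {
    i <- cats == cg
    data.frame(category = cg, n = sum(i),
               prevalence = 100 * mean(i),
               accuracy = if (any(i))
                 100 * mean(pred_female[i] == female[i]) else NA_real_)
  }))
  structure(list(accuracy = acc, auc = auc, sensitivity = sens,
                 specificity = spec,
                 confusion = c(tp = tp, fp = fp, fn = fn, tn = tn),
                 by_age = by_age, by_category = by_category,
                 n = length(scores)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> n=%d acc=%.1f%% AUC=%.3f sens=%s spec=%s\n",
    x$n, x$accuracy, x$auc,
    ifelse(is.na(x$sensitivity), "NA", sprintf("%.1f%%", x$sensitivity)),
    ifelse(is.na(x$specificity), "NA", sprintf("%.1f%%", x$specificity))))
  invisible(x)
}

#' Trapezoidal ROC area under the curve
#'
#' Computed via the rank (Mann-Whitney) identity, which equals the
#' trapezoidal area under the empirical ROC with tied scores averaged.
#'
#' @param scores Numeric scores, higher = more positive.
#' @param positive Logical truth.
#' @return AUC in `[0, 1]`, or `NA` if a class is absent.
#' @export
roc_auc <- function(scores, positive) {
  positive <- as.logical(positive)
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Per-lead and subject accuracy table
#'
#' @param cv A `spar_cv` with lead-level results.
#' @return data.frame with one row per lead plus a `Subject` row, columns
#'   `unit`, `accuracy`, `auc`.
#' @export
lead_accuracy_table <- function(cv) {
  stopifnot(inherits(cv, "spar_cv"))
  rows <- list()
  if (!is.null(cv$lead_reports)) {
    for (lead in names(cv$lead_reports)) {
      rp <- cv$lead_reports[[lead]]
      rows[[lead]] <- data.frame(unit = lead, accuracy = rp$accuracy,
                                 auc = rp$auc)
    }
  }
  rows[["Subject"]] <- data.frame(unit = "Subject",
                                  accuracy = cv$report$accuracy,
                                  auc = cv$report$auc)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Train a master stacked model on a full cohort
#'
#' Base k-NNs keep the whole training cohort as their reference set minus a
#' seeded internal validation split, whose out-of-sample posteriors train
#' the subject-level stacker. Used to score an external (unseen) cohort.
#'
#' @param features A `spar_features` object for the training cohort.
#' @param k,stack_size,seed As in [nested_cross_validate()].
#' @param val_frac Fraction held out internally to train the stacker.
#' @return A `spar_master_model`.
#' @export
train_master_model <- function(features, k = 20, stack_size = 25,
                               seed = 1L, val_frac = 0.15) {
  meta <- features$meta
  female <- meta$sex == "female"
  n <- nrow(meta)
  val_idx <- with_seed(seed, {
    v <- integer(0)
    for (cls in c(TRUE, FALSE)) {
      idx <- which(female == cls)
      v <- c(v, sample(idx, max(2L, round(length(idx) * val_frac))))
    }
    sort(v)
  })
  train_idx <- setdiff(seq_len(n), val_idx)
  post_val <- block_posteriors(features, train_idx, val_idx, female, k)
  planes_df <- unique(features$keys[, c("N", "k")])
  planes <- lapply(seq_len(nrow(planes_df)), function(i)
    projection_plane(planes_df$N[i], planes_df$k[i]))
  subj_val <- build_stack_features(post_val, "subject",
                                   leads = features$leads, planes = planes)
  stacker <- train_stacker(subj_val, female[val_idx], seed = seed,
                           size = stack_size)
  structure(list(features = features, train_idx = train_idx,
                 stacker = stacker, k = k, planes = planes,
                 seed = as.integer(seed)),
            class = "spar_master_model")
}

#' Score an external cohort with a master model
#'
#' @param model A `spar_master_model`.
#' @param new_features A `spar_features` object for the external cohort,
#'   computed with the same planes and binning.
#' @return data.frame record_id / score / label / category.
#' @export
score_cohort <- function(model, new_features) {
  stopifnot(inherits(model, "spar_master_model"),
            inherits(new_features, "spar_features"))
  female_train <- model$features$meta$sex == "female"
  keys <- model$features$keys$key
  if (!identical(sort(keys), sort(new_features$keys$key)))
    stop("feature blocks of the external cohort do not match the model")
  nq <- nrow(new_features$meta)
  post <- matrix(NA_real_, nrow = nq, ncol = length(keys),
                 dimnames = list(new_features$meta$record_id, keys))
  for (key in keys) {
    post[, key] <- knn_posterior(
      model$features$features[[key]][model$train_idx, , drop = FALSE],
      female_train[model$train_idx],
      new_features$features[[key]], k = model$k)
  }
  subj <- build_stack_features(post, "subject",
                               leads = model$features$leads,
                               planes = model$planes)
  sc <- predict_stacker(model$stacker, subj)
  data.frame(record_id = new_features$meta$record_id, score = sc,
             label = ifelse(sc > 0.5, "female", "male"),
             category = categorize_score(sc),
             stringsAsFactors = FALSE)
}
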