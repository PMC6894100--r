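# Convolutional text classifier used as an independent cross-check on
# histology extraction.
#
# Architecture: embedding lookup -> 1-D convolution (n_filters filters of
# width filter_width, ReLU) -> 1-max pooling over the token sequence ->
# fully connected layer -> softmax over the classes. Embeddings come
# from a skip-gram (word2vec-style) model trained with negative sampling
# on the corpus itself, or from random initialization. Everything is
# plain seeded R numerics, so training is deterministic on a single
# thread.

tokenize_text <- function(x) {
  stringr::str_extract_all(tolower(x), "[a-z0-9]+")
}

#' Train skip-gram word embeddings
#'
#' A word2vec-style skip-gram model with negative sampling, trained by
#' stochastic gradient descent over (center, context) pairs within a
#' symmetric window. Deterministic given the seed.
#'
#' @param documents A document table (or any data frame with a `text`
#'   column).
#' @param dim Embedding dimension.
#' @param window Context window half-width in tokens.
#' @param epochs Passes over the corpus.
#' @param negative Negative samples per positive pair.
#' @param lr Learning rate.
#' @param min_count Minimum token frequency kept in the vocabulary.
#' @param seed Integer seed.
#' @return An `lc_embeddings` object: `vocab` (character) and `vectors`
#'   (one row per token, `dim` columns, rownames = tokens).
#' @export
train_embeddings <- function(documents, dim = 50, window = 3, epochs = 3,
                             negative = 5, lr = 0.05, min_count = 1,
                             seed = 1L) {
  toks <- tokenize_text(documents$text)
  all_tokens <- unlist(toks)
  if (!length(all_tokens)) {
    abort("Corpus has an empty vocabulary.", class = "lungnlp_empty_input")
  }
  freq <- table(all_tokens)
  vocab <- names(freq)[freq >= min_count]
  if (!length(vocab)) {
    abort("No token meets min_count.", class = "lungnlp_empty_input")
  }
  V <- length(vocab)
  idx <- setNames(seq_len(V), vocab)
  # unigram^(3/4) negative-sampling distribution
  neg_p <- as.numeric(freq[vocab])^0.75
  neg_p <- neg_p / sum(neg_p)

  withr::with_seed(seed, {
    W_in <- matrix(runif(V * dim, -0.5, 0.5) / dim, V, dim)
    W_out <- matrix(0, V, dim)
    for (ep in seq_len(epochs)) {
      for (d in sample.int(length(toks))) {
        ids <- idx[toks[[d]]]
        ids <- ids[!is.na(ids)]
        L <- length(ids)
        if (L < 2L) next
        for (t in seq_len(L)) {
          lo <- max(1L, t - window); hi <- min(L, t + window)
          ctx <- ids[setdiff(lo:hi, t)]
          center <- ids[t]
          v <- W_in[center, ]
          for (c_id in ctx) {
            targets <- c(c_id, sample.int(V, negative, replace = TRUE,
                                          prob = neg_p))
            labels <- c(1, numeric(negative))
            U <- W_out[targets, , drop = FALSE]
            score <- 1 / (1 + exp(-drop(U %*% v)))
            g <- (score - labels) * lr
            dv <- drop(crossprod(U, g))
            W_out[targets, ] <- U - outer(g, v)
            v <- v - dv
          }
          W_in[center, ] <- v
        }
      }
    }
    rownames(W_in) <- vocab
    structure(list(vocab = vocab, vectors = W_in),
              class = "lc_embeddings")
  })
}

#' @export
print.lc_embeddings <- function(x, ...) {
  cat(sprintf("<lc_embeddings: %d tokens x %d dims>\n",
              length(x$vocab), ncol(x$vectors)))
  invisible(x)
}

#' Cosine similarity between two embedded tokens
#'
#' @param embeddings An `lc_embeddings`.
#' @param a,b Tokens.
#' @return Cosine similarity in `[-1, 1]`.
#' @export
embedding_similarity <- function(embeddings, a, b) {
  for (tok in c(a, b)) {
    if (!tok %in% embeddings$vocab) {
      abort(paste0("Token '", tok, "' is not in the vocabulary."),
            class = "lungnlp_domain_error")
    }
  }
  va <- embeddings$vectors[a, ]; vb <- embeddings$vectors[b, ]
  sum(va * vb) / sqrt(sum(va^2) * sum(vb^2))
}

#' CNN configuration
#'
#' Filters and filter width follow the reference architecture (128
#' filters of width 5); embedding dimension, sequence cap, optimizer
#' settings and seed are tunable.
#'
#' @param n_filters Number of convolution filters.
#' @param filter_width Filter width in tokens.
#' @param embedding_dim Embedding dimension (used when no pre-trained
#'   embeddings are supplied).
#' @param max_len Maximum token sequence length (longer documents are
#'   truncated, shorter ones padded).
#' @param epochs,lr Training epochs and Adagrad learning rate.
#' @param seed Integer seed.
#' @return An `lc_cnn_config` list.
#' @export
cnn_config <- function(n_filters = 128, filter_width = 5,
                       embedding_dim = 50, max_len = 256,
                       epochs = 10, lr = 0.1, seed = 1L) {
  stopifnot(n_filters > 0, filter_width > 0, embedding_dim > 0,
            max_len >= filter_width, epochs > 0, lr > 0)
  structure(list(n_filters = as.integer(n_filters),
                 filter_width = as.integer(filter_width),
                 embedding_dim = as.integer(embedding_dim),
                 max_len = as.integer(max_len),
                 epochs = as.integer(epochs), lr = lr,
                 seed = as.integer(seed)),
            class = "lc_cnn_config")
}

texts_to_ids <- function(texts, vocab_index, max_len, filter_width) {
  toks <- tokenize_text(texts)
  lapply(toks, function(tt) {
    ids <- unname(vocab_index[tt])
    ids[is.na(ids)] <- 1L          # <unk>
    ids <- head(ids, max_len)
    if (length(ids) < filter_width) {
      ids <- c(ids, rep(2L, filter_width - length(ids)))   # <pad>
    }
    ids
  })
}

cnn_forward <- function(ids, E, W, b, U, cc, fw) {
  L <- length(ids)
  d <- ncol(E)
  X <- E[ids, , drop = FALSE]
  n_win <- L - fw + 1L
  Xw <- matrix(0, n_win, fw * d)
  for (j in seq_len(fw)) {
    Xw[, ((j - 1L) * d + 1L):(j * d)] <- X[j:(j + n_win - 1L), , drop = FALSE]
  }
  S <- Xw %*% W + rep(b, each = n_win)
  H <- pmax(S, 0)
  pool_idx <- apply(H, 2L, which.max)
  p <- H[cbind(pool_idx, seq_along(pool_idx))]
  z <- drop(p %*% U) + cc
  z <- z - max(z)
  ez <- exp(z)
  probs <- ez / sum(ez)
  list(Xw = Xw, S = S, pool_idx = pool_idx, p = p, probs = probs)
}

#' Train the convolutional histology classifier
#'
#' @param data A data frame with a text column and a label column.
#' @param text,label Column names (strings) for the document text and the
#'   class label; the label is coerced to a factor whose levels define
#'   the softmax output dimension.
#' @param embeddings Optional `lc_embeddings` used (frozen) for the
#'   embedding layer; without it, embeddings are randomly initialized at
#'   `config$embedding_dim` and still frozen.
#' @param config An [cnn_config()].
#' @return An `lc_cnn_fit` with the learned weights, vocabulary, class
#'   levels and per-epoch training history.
#' @export
train_cnn <- function(data, text = "text", label = "label",
                      embeddings = NULL, config = cnn_config()) {
  texts <- data[[text]]
  y_fac <- if (is.factor(data[[label]])) data[[label]]
           else factor(data[[label]])
  y_fac <- droplevels(y_fac)
  K <- nlevels(y_fac)
  if (K < 2L) {
    abort("Training labels must contain at least two classes.",
          class = "lungnlp_domain_error")
  }
  y <- as.integer(y_fac)
  fw <- config$filter_width
  nf <- config$n_filters

  withr::with_seed(config$seed, {
    if (is.null(embeddings)) {
      vocab <- sort(unique(unlist(tokenize_text(texts))))
      d <- config$embedding_dim
      Evoc <- matrix(rnorm(length(vocab) * d, sd = 0.3), length(vocab), d)
    } else {
      vocab <- embeddings$vocab
      Evoc <- embeddings$vectors
      d <- ncol(Evoc)
    }
    # rows 1-2 are <unk> / <pad>
    E <- rbind(rnorm(d, sd = 0.1), rep(0, d), Evoc)
    vocab_index <- setNames(seq_along(vocab) + 2L, vocab)
    ids_list <- texts_to_ids(texts, vocab_index, config$max_len, fw)

    W <- matrix(rnorm(fw * d * nf, sd = sqrt(2 / (fw * d))), fw * d, nf)
    b <- numeric(nf)
    U <- matrix(rnorm(nf * K, sd = sqrt(1 / nf)), nf, K)
    cc <- numeric(K)
    gW <- matrix(1e-8, fw * d, nf); gb <- rep(1e-8, nf)
    gU <- matrix(1e-8, nf, K); gc <- rep(1e-8, K)
    lr <- config$lr
    history <- tibble(epoch = integer(), loss = numeric(),
                      accuracy = numeric())

    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(length(ids_list))
      tot_loss <- 0; correct <- 0L
      for (i in ord) {
        fwd <- cnn_forward(ids_list[[i]], E, W, b, U, cc, fw)
        probs <- fwd$probs
        tot_loss <- tot_loss - log(max(probs[y[i]], 1e-12))
        if (which.max(probs) == y[i]) correct <- correct + 1L
        dz <- probs
        dz[y[i]] <- dz[y[i]] - 1
        dU <- outer(fwd$p, dz)
        dp <- drop(U %*% dz)
        dH <- matrix(0, nrow(fwd$S), nf)
        dH[cbind(fwd$pool_idx, seq_len(nf))] <- dp
        dS <- dH * (fwd$S > 0)
        dW <- crossprod(fwd$Xw, dS)
        db <- colSums(dS)
        gW <- gW + dW^2; gb <- gb + db^2
        gU <- gU + dU^2; gc <- gc + dz^2
        W <- W - lr * dW / sqrt(gW)
        b <- b - lr * db / sqrt(gb)
        U <- U - lr * dU / sqrt(gU)
        cc <- cc - lr * dz / sqrt(gc)
      }
      history <- dplyr::bind_rows(history, tibble(
        epoch = ep, loss = tot_loss / length(ids_list),
        accuracy = correct / length(ids_list)))
    }

    structure(list(E = E, W = W, b = b, U = U, cc = cc,
                   vocab_index = vocab_index, levels = levels(y_fac),
                   config = config, history = history),
              class = "lc_cnn_fit")
  })
}

#' @export
print.lc_cnn_fit <- function(x, ...) {
  cat(sprintf(paste0("<lc_cnn_fit: %d filters x width %d, %d classes, ",
                     "final training accuracy %.3f>\n"),
              x$config$n_filters, x$config$filter_width,
              length(x$levels), utils::tail(x$history$accuracy, 1)))
  invisible(x)
}

#' Predict classes for documents
#'
#' Deterministic at inference (argmax of the softmax). A document whose
#' tokens are all out of vocabulary is predicted from unknown/padding
#' tokens with a warning.
#'
#' @param object An `lc_cnn_fit`.
#' @param new_data A data frame with the text column.
#' @param text Text column name.
#' @param ... Unused.
#' @return A tibble with `.pred_class` and one `.prob_<class>` column per
#'   class (rows sum to 1).
#' @export
predict.lc_cnn_fit <- function(object, new_data, text = "text", ...) {
  texts <- new_data[[text]]
  if (!length(texts)) {
    abort("No documents to predict.", class = "lungnlp_empty_input")
  }
  if (any(!nzchar(texts) | is.na(texts))) {
    abort("Cannot predict on empty document text.",
          class = "lungnlp_empty_input")
  }
  cfg <- object$config
  ids_list <- texts_to_ids(texts, object$vocab_index, cfg$max_len,
                           cfg$filter_width)
  if (any(vapply(ids_list, function(ii) all(ii <= 2L), logical(1)))) {
    warn("Some documents contain only out-of-vocabulary tokens; their predictions come from unknown/padding embeddings.")
  }
  probs <- t(vapply(ids_list, function(ii) {
    cnn_forward(ii, object$E, object$W, object$b, object$U, object$cc,
                cfg$filter_width)$probs
  }, numeric(length(object$levels))))
  out <- tibble(.pred_class = object$levels[max.col(probs,
                                                    ties.method = "first")])
  colnames(probs) <- paste0(".prob_", object$levels)
  dplyr::bind_cols(out, as_tibble(probs))
}

#' @export
#' @method tidy lc_cnn_fit
tidy.lc_cnn_fit <- function(x, ...) {
  x$history
}

#' @export
#' @method glance lc_cnn_fit
glance.lc_cnn_fit <- function(x, ...) {
  n_par <- length(x$W) + length(x$b) + length(x$U) + length(x$cc)
  tibble(
    n_classes = length(x$levels),
    n_filters = x$config$n_filters,
    filter_width = x$config$filter_width,
    epochs = x$config$epochs,
    n_parameters = n_par,
    final_loss = utils::tail(x$history$loss, 1),
    final_accuracy = utils::tail(x$history$accuracy, 1)
  )
}

#' @export
#' @method autoplot lc_cnn_fit
autoplot.lc_cnn_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$history, c("loss", "accuracy"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, title = "CNN training history") +
    ggplot2::theme_minimal()
}

#' Seeded train/test split of a cohort
#'
#' @param patient_ids Character vector of ids.
#' @param n_test Held-out test-set size.
#' @param seed Integer seed.
#' @return `list(train, test)` -- disjoint, exhaustive id sets.
#' @export
split_cohort <- function(patient_ids, n_test, seed = 1L) {
  patient_ids <- unique(patient_ids)
  if (n_test >= length(patient_ids)) {
    abort("n_test must be smaller than the cohort.",
          class = "lungnlp_config_error")
  }
  withr::with_seed(seed, {
    test <- sample(patient_ids, n_test)
    list(train = setdiff(patient_ids, test), test = test)
  })
}

#' Per-patient training frame for the classifier
#'
#' Concatenates each patient's eligible documents (histology document
#' selection under `window`) into one text and attaches the reference
#' histology label.
#'
#' @param documents,patients,reference Corpus and reference tables.
#' @param window [time_window()] for pathology/surgery eligibility.
#' @return A tibble `patient_id`, `text`, `label` (factor over the ten
#'   canonical histologies present).
#' @export
cnn_training_frame <- function(documents, patients, reference,
                               window = time_window(14, 90)) {
  eligible <- select_documents(documents, patients, "histology", window)
  texts <- eligible %>%
    arrange(.data$patient_id, .data$date, .data$doc_id) %>%
    group_by(.data$patient_id) %>%
    summarise(text = paste(.data$text, collapse = " "), .groups = "drop")
  out <- inner_join(texts,
                    reference[, c("patient_id", "histology")],
                    by = "patient_id")
  out <- out[!is.na(out$histology), ]
  out$label <- factor(out$histology,
                      levels = intersect(lc_histology_values(),
                                         unique(out$histology)))
  out[, c("patient_id", "text", "label")]
}

#' Cross-check rule-based and CNN histology results
#'
#' Partitions patients by the agreement pattern of the rule-based
#' extraction, the CNN prediction and the reference standard.
#' "Correct" uses the hierarchical histology match; the
#' `both_against_reference` bucket (both systems wrong and agreeing with
#' each other) flags candidate reference-standard errors.
#'
#' @param rule_results Tibble `patient_id`, `histology` (rule-based).
#' @param cnn_results Tibble `patient_id`, `histology` (CNN).
#' @param reference Reference tibble with `patient_id`, `histology`.
#' @return A tibble `patient_id`, `rule`, `cnn`, `reference`, `category`
#'   with category one of `both_match_reference`,
#'   `both_against_reference`, `rule_only_error`, `cnn_only_error`,
#'   `discordant_errors`.
#' @export
cross_check <- function(rule_results, cnn_results, reference) {
  ids <- reference$patient_id
  for (nm in c("rule_results", "cnn_results")) {
    tbl <- get(nm)
    missing_ids <- setdiff(ids, tbl$patient_id)
    if (length(missing_ids)) {
      abort(paste0(nm, " is missing patient id(s): ",
                   paste(head(missing_ids, 10), collapse = ", ")),
            class = "lungnlp_domain_error")
    }
  }
  df <- reference[, c("patient_id", "histology")] %>%
    rename(reference = "histology") %>%
    left_join(rename(rule_results[, c("patient_id", "histology")],
                     rule = "histology"), by = "patient_id") %>%
    left_join(rename(cnn_results[, c("patient_id", "histology")],
                     cnn = "histology"), by = "patient_id")
  rule_ok <- match_value("histology", df$reference, df$rule)
  cnn_ok <- match_value("histology", df$reference, df$cnn)
  same <- !is.na(df$rule) & !is.na(df$cnn) & df$rule == df$cnn
  df$category <- dplyr::case_when(
    rule_ok & cnn_ok ~ "both_match_reference",
    !rule_ok & !cnn_ok & same ~ "both_against_reference",
    !rule_ok & cnn_ok ~ "rule_only_error",
    rule_ok & !cnn_ok ~ "cnn_only_error",
    TRUE ~ "discordant_errors"
  )
  df[, c("patient_id", "rule", "cnn", "reference", "category")]
}
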