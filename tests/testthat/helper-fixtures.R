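# Shared fixtures and independent oracles used across the suite.

# Build a minimal exemplar tibble from a vector of categories.
make_exemplars <- function(categories, note_id = "n1",
                           prefix = "e") {
  n <- length(categories)
  tibble::tibble(
    exemplar_id = sprintf("%s%04d", prefix, seq_len(n)),
    note_id = note_id,
    text = sprintf("exemplar text %d.", seq_len(n)),
    n_sentences = 1L,
    category = categories,
    provenance = as.character(ifelse(categories == "none",
                                     "negative_sample", "human_initial")),
    annotator_ids = rep(list(character()), n))
}

# A tiny hand-built corpus: each note one free-text block with a known
# number of sentences.
make_notes <- function(sentence_counts, note_type = "obstetric_triage",
                       annotated = FALSE) {
  n <- length(sentence_counts)
  tibble::tibble(
    note_id = sprintf("tn%03d", seq_len(n)),
    note_type = rep_len(note_type, n),
    structured_sections = rep(list(tibble::tibble(header = "Vitals:",
                                                  text = "bp 120/70")), n),
    free_text = vapply(sentence_counts, function(k) {
      paste(sprintf("filler sentence number %d here.", seq_len(k)),
            collapse = " ")
    }, character(1)),
    annotated_flag = rep_len(annotated, n))
}

# Independent FNV-1a 32-bit implementation (pure R) used as the oracle
# for the hashed embedding's bucket positions.
fnv1a_r <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    # xor only touches the low byte (b < 256)
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b))
    # 32-bit modular multiply via 16-bit limbs to stay in double precision
    hl <- h %% 65536
    hh <- (h - hl) / 65536
    h <- (((hh * p) %% 65536) * 65536 + hl * p) %% 4294967296
  }
  h
}

# Brute-force confusion-matrix P/R/F1 oracle, independent of prf_report.
brute_prf <- function(y_true, y_pred, cats) {
  per <- lapply(cats, function(cl) {
    tp <- sum(y_true == cl & y_pred == cl)
    fp <- sum(y_true != cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    r <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    c(precision = p, recall = r, f1 = f)
  })
  do.call(rbind, per)
}

# Exhaustive cosine top-k oracle with stable tie-breaking by pool order.
brute_topk <- function(vectors, query, k) {
  sims <- apply(vectors, 2, function(v) {
    nu <- sqrt(sum(v^2)); nq <- sqrt(sum(query^2))
    if (nu == 0 || nq == 0) 0 else sum(v * query) / (nu * nq)
  })
  ord <- order(-sims, seq_along(sims))
  utils::head(ord, k)
}
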