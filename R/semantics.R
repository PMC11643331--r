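#' Semantic RDM from annotation tokens and word embeddings
#'
#' Each stimulus's vector is the unweighted mean of the embedding vectors of
#' its tokens of the requested class (verb or nonverb); the RDM holds the
#' cosine distance `1 - cos(v_i, v_j)` between stimulus vectors. Tokens
#' absent from the embedding table are dropped with a warning; a stimulus
#' losing all its tokens is an error.
#'
#' @param annotations data frame with columns `stimulus_id`, `token`,
#'   `class`.
#' @param embeddings token x dimension matrix with token rownames.
#' @param token_class `"verb"` or `"nonverb"`.
#' @param stimulus_ids optional stimulus order.
#' @return an `rdm` with meta `source = paste0(token_class, "_semantic")`.
#' @export
semantic_rdm <- function(annotations, embeddings,
                         token_class = c("verb", "nonverb"),
                         stimulus_ids = NULL) {
  token_class <- match.arg(token_class)
  vecs <- stimulus_vectors(annotations, embeddings, token_class, stimulus_ids)
  nrm <- sqrt(rowSums(vecs^2))
  if (any(nrm < 1e-12)) {
    stop_arg("zero-norm semantic vector for stimulus: ",
             paste(rownames(vecs)[nrm < 1e-12], collapse = ", "))
  }
  mat <- 1 - tcrossprod(vecs / nrm)
  diag(mat) <- 0
  rdm(mat, stimulus_ids = rownames(vecs),
      meta = list(source = paste0(token_class, "_semantic")))
}

# mean embedding vector per stimulus for one token class
stimulus_vectors <- function(annotations, embeddings, token_class,
                             stimulus_ids = NULL, classes = token_class) {
  ann <- annotations[annotations$class %in% classes, , drop = FALSE]
  known <- ann$token %in% rownames(embeddings)
  if (!all(known)) {
    warning(sum(!known), " annotation token(s) missing from the embedding ",
            "table were dropped", call. = FALSE)
    ann <- ann[known, , drop = FALSE]
  }
  if (is.null(stimulus_ids)) stimulus_ids <- unique(annotations$stimulus_id)
  vecs <- matrix(NA_real_, length(stimulus_ids), ncol(embeddings),
                 dimnames = list(stimulus_ids, NULL))
  for (id in stimulus_ids) {
    toks <- ann$token[ann$stimulus_id == id]
    if (!length(toks)) {
      stop_arg("stimulus '", id, "' has no resolvable ",
               paste(classes, collapse = "/"), " tokens")
    }
    vecs[id, ] <- colMeans(embeddings[toks, , drop = FALSE])
  }
  vecs
}

#' Inter-annotator agreement of semantic vectors
#'
#' For each stimulus, the Pearson correlation between the two annotators'
#' mean label vectors (all token classes pooled). Stimuli whose vector is
#' constant are reported as `NA`.
#'
#' @param ann_a,ann_b annotation data frames (`stimulus_id`, `token`,
#'   `class`), one per annotator, covering the same stimuli.
#' @param embeddings token x dimension matrix.
#' @return data frame (`stimulus_id`, `r`); summary mean/SD/range attached as
#'   attribute `"summary"`.
#' @export
annotator_agreement <- function(ann_a, ann_b, embeddings) {
  ids <- unique(ann_a$stimulus_id)
  if (!setequal(ids, unique(ann_b$stimulus_id))) {
    stop_arg("annotators must cover the same stimuli")
  }
  va <- stimulus_vectors(ann_a, embeddings, NULL, ids,
                         classes = unique(ann_a$class))
  vb <- stimulus_vectors(ann_b, embeddings, NULL, ids,
                         classes = unique(ann_b$class))
  r <- vapply(ids, function(id) {
    if (sd(va[id, ]) < 1e-12 || sd(vb[id, ]) < 1e-12) return(NA_real_)
    cor(va[id, ], vb[id, ])
  }, numeric(1))
  out <- data.frame(stimulus_id = ids, r = r, stringsAsFactors = FALSE)
  ok <- !is.na(r)
  attr(out, "summary") <- c(mean = mean(r[ok]), sd = sd(r[ok]),
                            min = min(r[ok]), max = max(r[ok]))
  out
}

#' Read and write token embedding tables
#'
#' TSV with a `token` column followed by `v1..vD` dimension columns.
#'
#' @param embeddings token x dimension matrix.
#' @param path file path.
#' @export
write_embedding_table <- function(embeddings, path) {
  df <- data.frame(token = rownames(embeddings), embeddings)
  colnames(df) <- c("token", paste0("v", seq_len(ncol(embeddings))))
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_embedding_table
#' @export
read_embedding_table <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  emb <- as.matrix(df[, -1, drop = FALSE])
  rownames(emb) <- df$token
  emb
}
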