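# Numeric encoding of feature records: booleans to 0/1 with missingness
# indicators, counts/positions z-scored with sentinel indicators,
# interactor names feature-hashed, POS one-hot over a closed tag set.

POS_TAGS <- c("VB", "VBD", "VBG", "VBN", "VBP", "VBZ",
              "NN", "NNS", "JJ", "OTHER")

NUMERIC_FEATS <- c("n_proteins", "interactor_position", "n_words_between",
                   "n_left_words", "n_right_words")
BOOL_FEATS <- c("is_negated", "link_path")

# Deterministic polynomial rolling hash of a string into 0..(m-1).
string_bucket <- function(s, m) {
  codes <- utf8ToInt(tolower(s))
  h <- 0
  for (cc in codes) h <- (h * 31 + cc) %% 2147483647
  as.integer(h %% m)
}

#' Fit a feature encoder on training records
#'
#' Learns the standardization constants (mean and standard deviation of
#' each count/position feature over its *defined* training values, i.e.
#' excluding `-1` sentinels) and fixes the interactor-name hash dimension
#' and the closed POS tag set. Apply the fitted encoder to any set of
#' records with [encode_features()]; test rows are always encoded with
#' training statistics only.
#'
#' @param records A `ppi_features` data frame (training rows only).
#' @param hash_dim Number of hash buckets for interactor names (default 64).
#' @return An object of class `ppi_encoder`.
#' @export
fit_encoder <- function(records, hash_dim = 64L) {
  stopifnot(is.data.frame(records), hash_dim >= 1L)
  stats <- lapply(NUMERIC_FEATS, function(f) {
    v <- records[[f]]
    v <- v[!is.na(v) & v != -1L]
    mu <- if (length(v)) mean(v) else 0
    sd <- if (length(v) > 1L) stats::sd(v) else 1
    if (!is.finite(sd) || sd == 0) sd <- 1
    c(mean = mu, sd = sd)
  })
  names(stats) <- NUMERIC_FEATS
  structure(list(hash_dim = as.integer(hash_dim), pos_tags = POS_TAGS,
                 stats = stats),
            class = "ppi_encoder")
}

#' Encode feature records as a numeric matrix
#'
#' Booleans map to 0/1 with a companion missingness column for `NA`;
#' counts and positions are z-scored with the encoder's training
#' statistics, the `-1` sentinel passing through a dedicated indicator
#' column (the standardized column holds 0 there); interactor names are
#' feature-hashed to `hash_dim` one-hot buckets; POS tags are one-hot
#' over the closed tag set, with unknown tags mapped to `OTHER` (a
#' warning is raised).
#'
#' @param enc A fitted `ppi_encoder`.
#' @param records A `ppi_features` data frame.
#' @return A numeric matrix with informative column names, one row per
#'   record.
#' @export
encode_features <- function(enc, records) {
  stopifnot(inherits(enc, "ppi_encoder"), is.data.frame(records))
  n <- nrow(records)
  cols <- list()

  for (f in BOOL_FEATS) {
    v <- records[[f]]
    cols[[f]] <- as.numeric(!is.na(v) & v)
    cols[[paste0(f, "_missing")]] <- as.numeric(is.na(v))
  }
  for (f in NUMERIC_FEATS) {
    v <- as.numeric(records[[f]])
    sent <- is.na(v) | v == -1
    st <- enc$stats[[f]]
    z <- (v - st[["mean"]]) / st[["sd"]]
    z[sent] <- 0
    cols[[paste0(f, "_z")]] <- z
    cols[[paste0(f, "_undef")]] <- as.numeric(sent)
  }
  # interactor name -> hashed one-hot
  hm <- matrix(0, n, enc$hash_dim,
               dimnames = list(NULL, paste0("int_hash_", seq_len(enc$hash_dim) - 1L)))
  nm <- records$interactor_name
  for (i in seq_len(n)) {
    if (!is.na(nm[i])) hm[i, string_bucket(nm[i], enc$hash_dim) + 1L] <- 1
  }
  # POS one-hot over closed set
  pos <- records$interactor_pos
  unknown <- !is.na(pos) & !(pos %in% enc$pos_tags)
  if (any(unknown)) {
    warning("unknown POS tag(s) mapped to OTHER: ",
            paste(unique(pos[unknown]), collapse = ", "), call. = FALSE)
    pos[unknown] <- "OTHER"
  }
  pm <- matrix(0, n, length(enc$pos_tags),
               dimnames = list(NULL, paste0("pos_", enc$pos_tags)))
  for (i in seq_len(n)) {
    if (!is.na(pos[i])) pm[i, match(pos[i], enc$pos_tags)] <- 1
  }
  out <- cbind(do.call(cbind, cols), hm, pm)
  rownames(out) <- NULL
  out
}

#' One-step encoding of feature records
#'
#' Convenience wrapper: fits an encoder on `records` (or uses a supplied
#' one) and returns the encoded matrix. For train/test splits, fit on the
#' training rows with [fit_encoder()] and apply to both with
#' [encode_features()] so that no test-set statistics leak into the
#' encoding.
#'
#' @inheritParams encode_features
#' @param enc Optional pre-fitted encoder.
#' @inheritParams fit_encoder
#' @return A list with `matrix` and the `encoder` used.
#' @export
vectorize <- function(records, enc = NULL, hash_dim = 64L) {
  if (is.null(enc)) enc <- fit_encoder(records, hash_dim = hash_dim)
  list(matrix = encode_features(enc, records), encoder = enc)
}
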