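# Confusion-matrix metrics, analytic random baselines, binned medians and
# the randomization tests.

#' Confusion matrix of a positional prediction
#'
#' @param pred predicted position set (integer vector in `1..L`).
#' @param truth true position set (integer vector in `1..L`).
#' @param L sequence length.
#' @return named integer vector `TP`, `FP`, `TN`, `FN`.
#' @export
confusion <- function(pred, truth, L) {
  pred <- unique(as.integer(pred))
  truth <- unique(as.integer(truth))
  if (length(pred) && (min(pred) < 1L || max(pred) > L))
    stop("pred positions out of range 1..L")
  if (length(truth) && (min(truth) < 1L || max(truth) > L))
    stop("truth positions out of range 1..L")
  TP <- length(intersect(pred, truth))
  FP <- length(setdiff(pred, truth))
  FN <- length(setdiff(truth, pred))
  c(TP = TP, FP = FP, TN = L - TP - FP - FN, FN = FN)
}

#' Classification metrics from confusion counts
#'
#' Sen = TP/(TP+FN), Spe = TN/(FP+TN), Acc = (TP+TN)/total,
#' PPV = TP/(TP+FP), F1 = harmonic mean of Sen and PPV. Undefined ratios
#' (0/0) are returned as `NA` and are excluded from downstream medians.
#'
#' @param TP,FP,TN,FN confusion counts, or `TP` may be the named vector
#'   returned by [confusion()].
#' @return named numeric vector `Sen`, `Spe`, `Acc`, `PPV`, `F1`.
#' @export
classification_metrics <- function(TP, FP = NULL, TN = NULL, FN = NULL) {
  if (is.null(FP) && length(TP) == 4L) {
    FP <- TP[["FP"]]; TN <- TP[["TN"]]; FN <- TP[["FN"]]; TP <- TP[["TP"]]
  }
  total <- TP + FP + TN + FN
  stopifnot(total > 0L)
  rat <- function(num, den) if (den > 0) num / den else NA_real_
  Sen <- rat(TP, TP + FN)
  Spe <- rat(TN, FP + TN)
  Acc <- (TP + TN) / total
  PPV <- rat(TP, TP + FP)
  F1 <- if (!is.na(Sen) && !is.na(PPV) && (Sen + PPV) > 0)
    2 * Sen * PPV / (Sen + PPV) else NA_real_
  c(Sen = Sen, Spe = Spe, Acc = Acc, PPV = PPV, F1 = F1)
}

#' Analytic baselines for a random predictor
#'
#' Expected metrics when `N_D = r_D * L` predicted sites are placed
#' uniformly at random on a sequence carrying `N_I = r_I * L` true sites:
#' Sen_r = r_D, Spe_r = 1 - r_D, PPV_r = r_I,
#' Acc_r = r_D (2 r_I - 1) + (1 - r_I).
#'
#' @param r_D fraction of predicted (disordered) sites.
#' @param r_I fraction of true (interface) sites.
#' @return named numeric vector `Sen_r`, `Spe_r`, `PPV_r`, `Acc_r`.
#' @export
random_baselines <- function(r_D, r_I) {
  stopifnot(r_D >= 0, r_D <= 1, r_I >= 0, r_I <= 1)
  c(Sen_r = r_D, Spe_r = 1 - r_D, PPV_r = r_I,
    Acc_r = r_D * (2 * r_I - 1) + (1 - r_I))
}

#' Per-cluster metrics record
#'
#' Evaluates a predicted region set against a true region set on one cluster
#' and attaches the analytic random baselines at the observed region sizes.
#'
#' @param pred,truth position sets on the reference sequence.
#' @param L reference length.
#' @param cluster_id optional identifier carried through.
#' @return one-row data.frame with counts, metrics and baselines.
#' @export
metrics_record <- function(pred, truth, L, cluster_id = NA_character_) {
  cm <- confusion(pred, truth, L)
  met <- classification_metrics(cm)
  base <- random_baselines(length(unique(pred)) / L,
                           length(unique(truth)) / L)
  data.frame(cluster_id = cluster_id, L = L,
             t(cm), t(met), t(base),
             r_D = length(unique(pred)) / L,
             r_I = length(unique(truth)) / L,
             stringsAsFactors = FALSE)
}

.log2_bin <- function(k) {
  stopifnot(all(k >= 1))
  ifelse(k <= 1, 1L, as.integer(ceiling(log2(k))) + 1L)
}

#' Binned medians over cluster keys
#'
#' `"log2"` binning groups integer keys into doubling bins
#' `{1}, {2}, {3,4}, {5..8}, {9..16}, ...`; `"even"` binning splits `[0, 1]`
#' into `n_bins` equal bins (keys equal to 1 fall in the last bin). Per
#' populated bin the median, mean and standard error of the mean (from the
#' value-to-value fluctuations inside the bin) are reported; `NA` values are
#' dropped first.
#'
#' @param values numeric vector.
#' @param keys numeric vector of the same length.
#' @param binning `"log2"` or `"even"`.
#' @param n_bins number of bins for `"even"` (default 20).
#' @return data.frame with `bin`, `key_lo`, `key_hi`, `n`, `median`, `mean`,
#'   `sem`; empty bins are omitted.
#' @export
binned_median <- function(values, keys, binning = c("log2", "even"),
                          n_bins = 20L) {
  binning <- match.arg(binning)
  ok <- !is.na(values) & !is.na(keys)
  values <- values[ok]
  keys <- keys[ok]
  if (binning == "log2") {
    bin <- .log2_bin(keys)
    lo <- ifelse(bin == 1L, 1, 2^(bin - 2L) + 1)
    hi <- 2^(bin - 1L)
  } else {
    stopifnot(all(keys >= 0 & keys <= 1))
    bin <- pmin(floor(keys * n_bins), n_bins - 1L) + 1L
    lo <- (bin - 1L) / n_bins
    hi <- bin / n_bins
  }
  out <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    v <- values[bin == b]
    data.frame(bin = b, key_lo = lo[match(b, bin)], key_hi = hi[match(b, bin)],
               n = length(v), median = median(v), mean = mean(v),
               sem = if (length(v) > 1L) sd(v) / sqrt(length(v)) else NA_real_)
  }))
  rownames(out) <- NULL
  out
}

.runs <- function(pos) {
  if (!length(pos)) return(list())
  pos <- sort(unique(pos))
  brk <- c(0L, which(diff(pos) > 1L), length(pos))
  lapply(seq_len(length(brk) - 1L), function(i)
    pos[(brk[i] + 1L):brk[i + 1L]])
}

# segments are kept non-overlapping and non-adjacent, so the multiset of
# maximal run lengths is preserved exactly
.place_segments <- function(seg_lengths, L, max_attempts = 10000L) {
  for (att in seq_len(max_attempts)) {
    blocked <- logical(L)
    ok <- TRUE
    pos <- integer(0)
    for (len in seg_lengths) {
      if (len > L) { ok <- FALSE; break }
      start <- sample.int(L - len + 1L, 1L)
      idx <- start:(start + len - 1L)
      if (any(blocked[idx])) { ok <- FALSE; break }
      blocked[max(1L, start - 1L):min(L, start + len)] <- TRUE
      pos <- c(pos, idx)
    }
    if (ok) return(sort(pos))
  }
  stop("could not place segments without overlap; use a longer sequence")
}

#' Randomized null versions of a disorder annotation
#'
#' Three randomization schemes for testing whether observed disorder
#' positions are informative: mode 1 translates each member structure's
#' maximal contiguous disordered segments to random non-overlapping
#' locations before taking the union; mode 2 replaces the union by a
#' uniform random subset of equal size; mode 3 translates the union's
#' maximal contiguous segments to random non-overlapping locations,
#' preserving segment lengths.
#'
#' @param x for mode 1, a list of per-member position sets; for modes 2 and
#'   3, a single position set (the union).
#' @param mode 1, 2 or 3.
#' @param L sequence length.
#' @param seed integer seed (required).
#' @param max_attempts rejection-sampling cap for segment placement.
#' @return randomized position set (for mode 1, the union of the randomized
#'   members).
#' @export
randomization_test <- function(x, mode, L, seed, max_attempts = 10000L) {
  stopifnot(mode %in% 1:3, !missing(seed))
  withr::with_seed(seed, {
    if (mode == 1) {
      stopifnot(is.list(x))
      sets <- lapply(x, function(pos) {
        segs <- lengths(.runs(pos))
        if (!length(segs)) return(integer(0))
        .place_segments(segs, L, max_attempts)
      })
      sort(unique(unlist(sets)))
    } else if (mode == 2) {
      pos <- unique(as.integer(x))
      sort(sample.int(L, length(pos)))
    } else {
      segs <- lengths(.runs(x))
      if (!length(segs)) return(integer(0))
      .place_segments(segs, L, max_attempts)
    }
  })
}

#' Read a generic per-residue annotation table
#'
#' TSV with columns `position` and `flag` (0/1), as produced by external
#' per-residue predictors, so their outputs can be scored with
#' [confusion()] and [classification_metrics()].
#'
#' @param path TSV file.
#' @return integer vector of flagged positions.
#' @export
read_annotation_flags <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(c("position", "flag") %in% names(df)))
  sort(as.integer(df$position[df$flag != 0]))
}
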