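# Synthetic PDB fixture clusters with planted ground truth: a self-avoiding
# Calpha trace shared by all members, nested (or disjoint) interface patches
# realised by partner chains, elevated B-factors anticipating the next
# interface, and missing segments emitted as REMARK 465.

.AA1TO3 <- setNames(names(.AA3TO1), unname(.AA3TO1))
.AA20 <- unname(.AA3TO1)

#' Specification of a synthetic cluster
#'
#' Collects and validates the generator parameters. The defaults describe
#' one protein family observed in several crystals: a 120-residue chain, a
#' nested ladder of three planted interfaces (one bound member each, plus
#' one unbound member), soft-disorder signal of 3 sigma planted at the
#' residues of the next interface to form, an always-missing N-terminal
#' segment (intrinsic disorder) and a sometimes-missing segment
#' (disorder-to-order), and a 2% substitution rate between members.
#'
#' @param L sequence length (>= 40).
#' @param n_interfaces number of planted distinct interfaces (>= 1).
#' @param n_members number of member structures; defaults to
#'   `n_interfaces + 1` (one unbound member plus one per interface).
#' @param nesting logical; nested ladder (`TRUE`) or disjoint patches.
#' @param delta_b planted soft-disorder effect size in sigma units (>= 0).
#' @param missing_segments list of `c(start, length, fraction)` triples;
#'   each segment is emitted as REMARK 465 in that fraction of members.
#' @param mutation_rate per-residue substitution probability (< 0.1).
#' @param partner_type `"protein"` or `"dna"` partner chains.
#' @param seed integer seed.
#' @return object of class `SyntheticSpec`.
#' @export
synthetic_spec <- function(L = 120L, n_interfaces = 3L, n_members = NULL,
                           nesting = TRUE, delta_b = 3,
                           missing_segments = list(c(1, 4, 1), c(6, 6, 0.5)),
                           mutation_rate = 0.02,
                           partner_type = c("protein", "dna"), seed = 1L) {
  partner_type <- match.arg(partner_type)
  if (is.null(n_members)) n_members <- n_interfaces + 1L
  stopifnot(L >= 40L, n_interfaces >= 1L, n_members >= n_interfaces + 1L,
            delta_b >= 0, mutation_rate >= 0, mutation_rate < 0.1)
  miss_end <- 0L
  for (seg in missing_segments) {
    stopifnot(length(seg) == 3L, seg[1] >= 1, seg[2] >= 1,
              seg[3] >= 0, seg[3] <= 1, seg[1] + seg[2] - 1 <= L)
    miss_end <- max(miss_end, seg[1] + seg[2] - 1)
  }
  inc <- floor(0.05 * L) + 2L
  start <- miss_end + 4L
  need <- if (nesting) start + n_interfaces * inc - 1L
          else start + n_interfaces * (inc + 3L) - 4L
  if (need > L)
    stop("L too short for ", n_interfaces, " planted interfaces (needs >= ",
         need, ")")
  structure(
    list(L = as.integer(L), n_interfaces = as.integer(n_interfaces),
         n_members = as.integer(n_members), nesting = nesting,
         delta_b = delta_b, missing_segments = missing_segments,
         mutation_rate = mutation_rate, partner_type = partner_type,
         seed = as.integer(seed), interface_start = start, increment = inc),
    class = "SyntheticSpec"
  )
}

.saw_trace <- function(L) {
  step <- 3.8
  min_d2 <- 4.0^2
  xyz <- matrix(NA_real_, L, 3L)
  xyz[1L, ] <- c(0, 0, 0)
  dir <- c(1, 0, 0)
  i <- 2L
  fails <- 0L
  while (i <= L) {
    ok <- FALSE
    for (att in seq_len(60L)) {
      nd <- dir + 0.35 * rnorm(3L)
      nd <- nd / sqrt(sum(nd^2))
      cand <- xyz[i - 1L, ] + step * nd
      if (i > 2L) {
        prev <- xyz[seq_len(i - 2L), , drop = FALSE]
        d2 <- (prev[, 1] - cand[1])^2 + (prev[, 2] - cand[2])^2 +
          (prev[, 3] - cand[3])^2
        if (min(d2) < min_d2) next
      }
      xyz[i, ] <- cand
      dir <- nd
      ok <- TRUE
      break
    }
    if (ok) {
      i <- i + 1L
    } else {
      fails <- fails + 1L
      if (fails > 500L) stop("self-avoiding trace placement failed")
      i <- max(2L, i - 2L)  # backtrack and retry
    }
  }
  xyz
}

#' Generate a self-avoiding reference Calpha trace
#'
#' Consecutive Calpha spacing is exactly 3.8 A; non-consecutive residues are
#' kept at least 4.0 A apart. Deterministic for a given seed.
#'
#' @param L number of residues (>= 20).
#' @param seed integer seed.
#' @return numeric `L x 3` coordinate matrix.
#' @export
generate_reference_structure <- function(L, seed = 1L) {
  stopifnot(L >= 20L)
  withr::with_seed(seed, .saw_trace(L))
}

.plant_sets <- function(L, n_interfaces, nesting, start, inc) {
  if (nesting) {
    lapply(seq_len(n_interfaces), function(k) start:(start + k * inc - 1L))
  } else {
    gap <- 3L
    lapply(seq_len(n_interfaces), function(k) {
      s <- start + (k - 1L) * (inc + gap)
      s:(s + inc - 1L)
    })
  }
}

#' Plant distinct interface patches on a sequence
#'
#' Produces `n_interfaces` position sets whose pairwise symmetric
#' differences all exceed 5% of `L`: a nested ladder
#' `I_1 subset I_2 subset ...` in nesting mode, or well-separated disjoint
#' patches otherwise.
#'
#' @param L sequence length.
#' @param n_interfaces number of interfaces.
#' @param nesting logical.
#' @param seed unused (placement is deterministic) but kept for a stable
#'   calling convention.
#' @param start first planted position (default 15).
#' @return list of integer position sets.
#' @export
plant_interfaces <- function(L, n_interfaces, nesting = TRUE, seed = 1L,
                             start = 15L) {
  inc <- floor(0.05 * L) + 2L
  need <- if (nesting) start + n_interfaces * inc - 1L
          else start + n_interfaces * (inc + 3L) - 4L
  if (need > L) stop("cannot satisfy separation constraints: L too short")
  .plant_sets(L, n_interfaces, nesting, start, inc)
}

.unit <- function(v) v / sqrt(sum(v^2))

.tangent <- function(xyz, p) {
  L <- nrow(xyz)
  .unit(xyz[min(p + 1L, L), ] - xyz[max(p - 1L, 1L), ])
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# place one partner pseudo-atom near position p such that it contacts p
# (at `dist` A) and no other residue of the chain within 5 A
.partner_point <- function(xyz, p, obs_pos, dist = 4.5) {
  t <- .tangent(xyz, p)
  axes <- list(c(0, 0, 1), c(0, 1, 0), c(1, 0, 0))
  cands <- list()
  for (e in axes) {
    if (abs(sum(t * e)) > 0.95) next
    u <- .unit(.cross3(t, e))
    cands <- c(cands, list(u, -u))
  }
  others <- obs_pos[obs_pos != p]
  for (d in c(dist, 4.2, 4.8)) {
    for (u in cands) {
      pt <- xyz[p, ] + d * u
      d2 <- (xyz[others, 1] - pt[1])^2 + (xyz[others, 2] - pt[2])^2 +
        (xyz[others, 3] - pt[3])^2
      if (all(d2 > 5.0^2 + 0.1)) return(pt)
    }
  }
  NULL
}

.make_protein_chain <- function(entry_id, chain_id, letters1, xyz, B,
                                missing_pos) {
  L <- length(letters1)
  is_missing <- seq_len(L) %in% missing_pos
  x <- xyz[, 1]; y <- xyz[, 2]; z <- xyz[, 3]
  x[is_missing] <- NA; y[is_missing] <- NA; z[is_missing] <- NA
  B[is_missing] <- NA
  names3 <- unname(.AA1TO3[letters1])
  names3[is.na(names3)] <- "UNK"
  residues <- data.frame(
    author_number = as.character(seq_len(L)), name = names3,
    one_letter = letters1, x = x, y = y, z = z, bfactor = B,
    is_missing = is_missing, stringsAsFactors = FALSE
  )
  obs <- !is_missing
  if (any(obs)) {
    atoms <- data.frame(
      elety = "CA", element = "C",
      author_number = as.character(which(obs)),
      x = x[obs], y = y[obs], z = z[obs], bfactor = B[obs],
      resid = names3[obs], stringsAsFactors = FALSE
    )
  } else {
    atoms <- NULL
  }
  structure(
    list(entry_id = entry_id, chain_id = chain_id,
         molecule_class = "protein", residues = residues,
         sequence = paste(letters1, collapse = ""), atoms = atoms),
    class = "ChainStructure"
  )
}

.make_partner_chain <- function(entry_id, chain_id, pts, type) {
  n <- nrow(pts)
  if (type == "protein") {
    residues <- data.frame(
      author_number = as.character(seq_len(n)), name = "GLY",
      one_letter = "G", x = pts[, 1], y = pts[, 2], z = pts[, 3],
      bfactor = 30, is_missing = FALSE, stringsAsFactors = FALSE
    )
    atoms <- data.frame(
      elety = "CA", element = "C", author_number = as.character(seq_len(n)),
      x = pts[, 1], y = pts[, 2], z = pts[, 3], bfactor = 30,
      resid = "GLY", stringsAsFactors = FALSE
    )
    cls <- "protein"
    seq1 <- strrep("G", n)
  } else {
    # 4 heavy pseudo-atoms per nucleotide, wrapped around each anchor point
    atoms <- do.call(rbind, lapply(seq_len(n), function(i) {
      ctr <- pts[i, ]
      data.frame(
        elety = c("P", "O5'", "C4'", "N1"),
        element = c("P", "O", "C", "N"),
        author_number = as.character(i),
        x = ctr[1] + c(0, 1.4, -1.4, 0),
        y = ctr[2] + c(0, 0.6, 0.6, -1.4),
        z = ctr[3] + c(0, 0, 0, 0.4),
        bfactor = 30, resid = "DA", stringsAsFactors = FALSE
      )
    }))
    residues <- data.frame(
      author_number = as.character(seq_len(n)), name = "DA", one_letter = "X",
      x = pts[, 1], y = pts[, 2], z = pts[, 3], bfactor = 30,
      is_missing = FALSE, stringsAsFactors = FALSE
    )
    cls <- "dna"
    seq1 <- strrep("X", n)
  }
  structure(
    list(entry_id = entry_id, chain_id = chain_id, molecule_class = cls,
         residues = residues, sequence = seq1, atoms = atoms),
    class = "ChainStructure"
  )
}

#' Generate a synthetic cluster of PDB entries with known ground truth
#'
#' Builds one unbound member plus bound members carrying the successive
#' planted interfaces (extra members recycle them). All members share a
#' self-avoiding reference trace; bound members get a partner chain placed
#' so that exactly the planted residues satisfy the 5 A Calpha contact rule
#' (protein partners) or occlude surface area (DNA partners). True
#' B-factors are baseline noise (sd 1 in normalized units, mean 30 A^2 on
#' the raw scale) plus `delta_b` at the residues of the next planted
#' interface yet to form. Missing segments are emitted as REMARK 465 in the
#' requested fraction of members, and member sequences are mutated at
#' `mutation_rate`.
#'
#' @param spec a `SyntheticSpec` from [synthetic_spec()].
#' @param dir optional directory: when given, one PDB file per member plus
#'   a `truth.json` are written there.
#' @return list with `entries` (list of `EntryStructure`), `truth` (planted
#'   interfaces, per-member soft/missing sets, expected NDI and hierarchy
#'   chain) and `spec`.
#' @export
generate_cluster <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  withr::with_seed(spec$seed, .generate_cluster_impl(spec, dir))
}

.generate_cluster_impl <- function(spec, dir) {
  L <- spec$L
  n <- spec$n_interfaces
  xyz <- .saw_trace(L)
  interfaces <- .plant_sets(L, n, spec$nesting, spec$interface_start,
                            spec$increment)
  ref_letters <- sample(.AA20, L, replace = TRUE)

  # which members carry each missing segment
  seg_members <- lapply(spec$missing_segments, function(seg) {
    k <- max(0L, min(spec$n_members, round(seg[3] * spec$n_members)))
    if (k == 0L) integer(0) else sort(sample.int(spec$n_members, k))
  })

  # interface carried by each member (0 = unbound)
  carried <- c(0L, seq_len(n))
  extra <- spec$n_members - (n + 1L)
  if (extra > 0L) carried <- c(carried, rep_len(seq_len(n), extra))

  entries <- list()
  truth_members <- list()
  for (m in seq_len(spec$n_members)) {
    entry_id <- sprintf("sy%02d", m)
    k <- carried[m]
    planted <- if (k >= 1L) interfaces[[k]] else integer(0)

    # next interface yet to form on this member
    nxt <- if (k < n) {
      if (spec$nesting) setdiff(interfaces[[k + 1L]], planted)
      else interfaces[[k + 1L]]
    } else integer(0)

    missing_pos <- sort(unique(unlist(Map(function(seg, who) {
      if (m %in% who) seg[1]:(seg[1] + seg[2] - 1) else integer(0)
    }, spec$missing_segments, seg_members))))

    # substitutions are placed away from the planted patches so that the
    # planted ground truth survives annotation transfer by alignment
    protected <- sort(unique(unlist(lapply(interfaces, function(s)
      unique(pmin(pmax(rep(s, each = 5L) + (-2:2), 1L), L))))))
    letters1 <- ref_letters
    mut <- setdiff(which(runif(L) < spec$mutation_rate), protected)
    for (p in mut) letters1[p] <- sample(setdiff(.AA20, letters1[p]), 1L)

    b_true <- rnorm(L)
    b_true[nxt] <- b_true[nxt] + spec$delta_b
    B <- 30 + 8 * b_true

    chainA <- .make_protein_chain(entry_id, "A", letters1, xyz, B, missing_pos)
    chains <- list(A = chainA)

    if (length(planted)) {
      obs_pos <- which(!chainA$residues$is_missing)
      pts <- matrix(NA_real_, length(planted), 3L)
      for (i in seq_along(planted)) {
        pt <- .partner_point(xyz, planted[i], obs_pos)
        if (is.null(pt))
          stop("could not place partner atom for position ", planted[i],
               "; try another seed")
        pts[i, ] <- pt
      }
      chains$B <- .make_partner_chain(entry_id, "B", pts, spec$partner_type)
    }

    entries[[entry_id]] <- structure(
      list(entry_id = entry_id, chains = chains,
           resolution = 1.5 + 0.05 * (m - 1L),
           r_value = 0.15 + 0.005 * (m - 1L),
           method = "X-RAY DIFFRACTION", is_xray = TRUE),
      class = "EntryStructure"
    )
    truth_members[[entry_id]] <- list(
      label = chain_label(entry_id, "A"),
      interface = planted,
      soft = setdiff(nxt, missing_pos),
      missing = missing_pos
    )
  }

  truth <- list(
    L = L, ndi = n, nesting = spec$nesting,
    interfaces = interfaces,
    hierarchy_chain = vapply(seq_len(n), function(k)
      truth_members[[which(carried == k)[1L]]]$label, character(1)),
    members = truth_members
  )

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (e in entries)
      write_pdb(e, file.path(dir, paste0(e$entry_id, ".pdb")))
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(entries = entries, truth = truth, spec = spec)
}
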