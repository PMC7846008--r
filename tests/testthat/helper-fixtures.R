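# Shared fixture builders and independent oracles. Everything is generated
# in code; no binary fixtures.

# minimal protein chain on a straight extended trace
straight_chain <- function(entry_id, chain_id, letters1, B = NULL,
                           missing_pos = integer(0), offset = c(0, 0, 0),
                           spacing = 3.8) {
  L <- length(letters1)
  if (is.null(B)) B <- rep(30, L)
  xyz <- cbind(offset[1] + spacing * (seq_len(L) - 1L), offset[2], offset[3])
  softdis:::.make_protein_chain(entry_id, chain_id, letters1, xyz, B,
                                missing_pos)
}

fake_entry <- function(chains, entry_id = "test", resolution = 2.0,
                       r_value = 0.2) {
  names(chains) <- vapply(chains, `[[`, character(1), "chain_id")
  structure(
    list(entry_id = entry_id, chains = chains, resolution = resolution,
         r_value = r_value, method = "X-RAY DIFFRACTION", is_xray = TRUE),
    class = "EntryStructure"
  )
}

# a Cluster object built directly from mapped member sets, for unit tests of
# the region algebra without going through alignment
fake_cluster <- function(members, L, reference_structure = NULL,
                         cluster_id = "fake_A") {
  mem <- lapply(seq_along(members), function(i) {
    m <- members[[i]]
    soft <- if (is.null(m$soft)) list("1" = integer(0)) else m$soft
    interface <- if (is.null(m$interface)) integer(0) else m$interface
    list(
      label = if (is.null(m$label)) sprintf("m%02d_A", i) else m$label,
      bound = length(interface) > 0L,
      covered = if (is.null(m$covered)) seq_len(L) else m$covered,
      missing = if (is.null(m$missing)) integer(0) else m$missing,
      soft = soft,
      interface = interface
    )
  })
  structure(
    list(cluster_id = cluster_id,
         reference_sequence = strrep("A", L),
         reference_structure = reference_structure,
         members = mem,
         n_structures = length(mem),
         n_unbound = sum(!vapply(mem, `[[`, logical(1), "bound"))),
    class = "Cluster"
  )
}

# independent breadth-first-search component counter over a contact graph
bfs_components <- function(xyz, cutoff) {
  n <- nrow(xyz)
  if (!n) return(0L)
  seen <- logical(n)
  comp <- 0L
  for (s in seq_len(n)) {
    if (seen[s]) next
    comp <- comp + 1L
    queue <- s
    seen[s] <- TRUE
    while (length(queue)) {
      v <- queue[1L]
      queue <- queue[-1L]
      d2 <- (xyz[, 1] - xyz[v, 1])^2 + (xyz[, 2] - xyz[v, 2])^2 +
        (xyz[, 3] - xyz[v, 3])^2
      nb <- which(d2 <= cutoff^2 + 1e-9 & !seen)
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
  }
  comp
}

# exhaustive single-linkage clustering at the identity/length thresholds
single_linkage_partition <- function(seqs, id_min = 0.9,
                                     len_ratio_min = 0.9) {
  n <- length(seqs)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      pid <- pairwise_identity(seqs[i], seqs[j])
      if (pid["identity"] >= id_min && pid["length_ratio"] >= len_ratio_min) {
        ri <- find(i)
        rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# annotate every member chain A of a generated synthetic cluster and build
# the Cluster object
cluster_from_synthetic <- function(gen, thetas = c(0.5, 1, 2, 3),
                                   diff_frac = 0.05) {
  anns <- list()
  structs <- list()
  for (e in gen$entries) {
    ch <- e$chains$A
    ann <- annotate_chain(e, ch, thetas = thetas)
    anns[[ann$label]] <- ann
    structs[[ann$label]] <- ch
  }
  make_cluster(anns, structs)
}

random_aa_seq <- function(L) {
  paste(sample(softdis:::.AA20, L, replace = TRUE), collapse = "")
}

mutate_seq <- function(s, n_mut) {
  x <- strsplit(s, "")[[1]]
  pos <- sample(length(x), n_mut)
  for (p in pos) x[p] <- sample(setdiff(softdis:::.AA20, x[p]), 1L)
  paste(x, collapse = "")
}
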