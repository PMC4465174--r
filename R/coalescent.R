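## Structured-coalescent engine: backward-in-time isolation-with-migration
## with secondary-contact migration windows and locus-specific permeability.
## Time is in coalescent units of 2*N0 generations; deme sizes are relative
## to N0; M = 4*N0*m is the scaled migration rate, applied per lineage at
## rate M*s/2 during a contact window.

#' Simulate one locus genealogy under the structured coalescent
#'
#' Backward in time: within-deme coalescence of k lineages at rate
#' `choose(k,2)/size`; during a contact window `[0, end_time]` each lineage
#' in either connected deme switches demes at rate `rate_per_lineage`
#' (= M*s/2); demes merge at scheduled times (within-species merges and
#' species-tree splits). The caller owns the RNG state (`set.seed`
#' upstream); identical state yields an identical tree.
#'
#' @param deme_sizes named numeric vector: relative deme sizes.
#' @param tip_deme character vector assigning each sampled lineage (tip) to
#'   a deme; names become tip labels.
#' @param merges data.frame with `time`, `from`, `to` (deme ids), sorted or
#'   not; at `time` all lineages in `from` move to `to` and `from` ceases.
#' @param contacts data.frame with `deme_a`, `deme_b`, `end_time`,
#'   `rate_per_lineage` (zero rows allowed).
#' @param tip_species optional species label per tip (for migrant flags and
#'   cross-species coalescence records); defaults to the deme id.
#' @return list: `n_tips`, `edge` (2-column matrix, ape orientation),
#'   `edge.length`, `node_time`, `tip_label`, `tip_deme`, `migrant_tip`
#'   (logical: lineage crossed demes of different species during a contact
#'   window), `cross_coalescences` (data.frame time/post_contact).
#' @export
simulate_genealogy <- function(deme_sizes, tip_deme, merges = NULL,
                               contacts = NULL, tip_species = NULL) {
  n <- length(tip_deme)
  if (n < 2L) abort_input("need >= 2 sampled lineages")
  if (is.null(names(deme_sizes))) abort_config("deme_sizes must be named")
  if (any(deme_sizes <= 0)) abort_config("deme sizes must be positive")
  if (!all(tip_deme %in% names(deme_sizes)))
    abort_config("tip assigned to unknown deme")
  tip_label <- names(tip_deme)
  if (is.null(tip_label)) tip_label <- paste0("t", seq_len(n))
  if (is.null(tip_species)) tip_species <- tip_deme
  deme_sp <- NULL  # species of a deme inferred from contacts only when needed
  if (is.null(merges))
    merges <- data.frame(time = numeric(), from = character(),
                         to = character())
  if (is.null(contacts))
    contacts <- data.frame(deme_a = character(), deme_b = character(),
                           end_time = numeric(), rate_per_lineage = numeric())
  merges <- merges[order(merges$time), , drop = FALSE]
  breakpoints <- sort(unique(c(merges$time, contacts$end_time)))

  alive <- names(deme_sizes)
  contact_dead <- rep(FALSE, nrow(contacts))
  lin_deme <- unname(tip_deme)
  lin_node <- seq_len(n)
  lin_tips <- as.list(seq_len(n))
  node_time <- c(rep(0, n), rep(NA_real_, n - 1L))
  edge <- matrix(0L, 2L * (n - 1L), 2L)
  edge_len <- numeric(2L * (n - 1L))
  next_node <- n + 1L
  e_ptr <- 0L
  migrant <- rep(FALSE, n)
  cross_times <- numeric()
  t <- 0

  species_of_tips <- function(tips) unique(tip_species[tips])

  apply_merges_at <- function(tm) {
    rows <- which(abs(merges$time - tm) < 1e-12)
    for (r in rows) {
      from <- merges$from[r]; to <- merges$to[r]
      if (!from %in% alive) next
      if (!to %in% alive) abort_config(sprintf("merge target %s not alive", to))
      lin_deme[lin_deme == from] <<- to
      alive <<- setdiff(alive, from)
      contact_dead[contacts$deme_a == from | contacts$deme_b == from] <<- TRUE
    }
  }

  repeat {
    k <- length(lin_node)
    if (k == 1L) break
    demes_now <- unique(lin_deme)
    kd <- vapply(demes_now, function(d) sum(lin_deme == d), numeric(1))
    coal_rate <- kd * (kd - 1) / 2 / deme_sizes[demes_now]
    act <- which(!contact_dead & contacts$end_time > t &
                 contacts$deme_a %in% alive & contacts$deme_b %in% alive)
    mig_rate <- vapply(act, function(ci)
      (sum(lin_deme == contacts$deme_a[ci]) +
       sum(lin_deme == contacts$deme_b[ci])) *
        contacts$rate_per_lineage[ci], numeric(1))
    R <- sum(coal_rate) + sum(mig_rate)
    nb <- breakpoints[breakpoints > t + 1e-15]
    next_bp <- if (length(nb)) nb[1] else Inf
    if (R <= 0) {
      if (!is.finite(next_bp))
        abort_config("lineages isolated forever: no coalescence possible")
      t <- next_bp
      apply_merges_at(t)
      next
    }
    dt <- rexp(1, R)
    if (t + dt >= next_bp) {
      t <- next_bp
      apply_merges_at(t)
      next
    }
    t <- t + dt
    u <- runif(1) * R
    placed <- FALSE
    for (di in seq_along(demes_now)) {
      if (u < coal_rate[di]) {
        idx <- which(lin_deme == demes_now[di])
        pair <- if (length(idx) == 2L) idx else sample(idx, 2L)
        a <- pair[1]; b <- pair[2]
        spA <- species_of_tips(lin_tips[[a]])
        spB <- species_of_tips(lin_tips[[b]])
        if (!setequal(spA, union(spA, spB)) || !setequal(spB, union(spA, spB)))
          cross_times <- c(cross_times, t)
        node_time[next_node] <- t
        edge[e_ptr + 1L, ] <- c(next_node, lin_node[a])
        edge[e_ptr + 2L, ] <- c(next_node, lin_node[b])
        edge_len[e_ptr + 1L] <- t - node_time[lin_node[a]]
        edge_len[e_ptr + 2L] <- t - node_time[lin_node[b]]
        e_ptr <- e_ptr + 2L
        lin_node[a] <- next_node
        lin_tips[[a]] <- c(lin_tips[[a]], lin_tips[[b]])
        lin_node <- lin_node[-b]
        lin_deme <- lin_deme[-b]
        lin_tips[[b]] <- NULL
        next_node <- next_node + 1L
        placed <- TRUE
        break
      }
      u <- u - coal_rate[di]
    }
    if (placed) next
    for (mi in seq_along(act)) {
      if (u < mig_rate[mi]) {
        ci <- act[mi]
        a_d <- contacts$deme_a[ci]; b_d <- contacts$deme_b[ci]
        idx <- which(lin_deme %in% c(a_d, b_d))
        li <- if (length(idx) == 1L) idx else sample(idx, 1L)
        from <- lin_deme[li]
        lin_deme[li] <- if (from == a_d) b_d else a_d
        migrant[lin_tips[[li]]] <- TRUE
        placed <- TRUE
        break
      }
      u <- u - mig_rate[mi]
    }
    if (!placed) next  # numerical edge: redraw
  }
  contact_end <- if (nrow(contacts)) max(contacts$end_time) else 0
  list(n_tips = n, edge = edge, edge.length = edge_len,
       node_time = node_time, tip_label = tip_label,
       tip_deme = unname(tip_deme), migrant_tip = migrant,
       cross_coalescences = data.frame(
         time = cross_times, post_contact = cross_times <= contact_end))
}

#' Drop infinite-sites mutations on a genealogy
#'
#' Each branch receives `Poisson(theta/2 * length)` mutations; every
#' mutation occupies a distinct uniformly drawn alignment column (a
#' collision triggers a redraw, implemented as sampling without
#' replacement). The ancestral base is `A`; each derived base is drawn
#' from `{C, G, T}`. The caller owns the RNG state.
#'
#' @param gen genealogy from [simulate_genealogy()].
#' @param theta per-locus scaled mutation rate (4*N0*mu*length).
#' @param length alignment columns L.
#' @return named character vector of tip sequences (length-L strings).
#' @export
drop_mutations <- function(gen, theta, length) {
  L <- as.integer(length)
  ne <- nrow(gen$edge)
  m_e <- rpois(ne, theta / 2 * gen$edge.length)
  total <- sum(m_e)
  if (total > L)
    abort_simulation(sprintf(
      "%d mutations exceed %d columns; increase locus length", total, L))
  cols <- if (total > 0) sample.int(L, total) else integer()
  base <- if (total > 0) sample(c("C", "G", "T"), total, replace = TRUE)
          else character()
  # per-node carried mutation indices, propagated root -> tips
  n <- gen$n_tips
  carried <- vector("list", 2L * n - 1L)
  edge_mut <- split(seq_len(total),
                    factor(rep(seq_len(ne), m_e), levels = seq_len(ne)))
  ord <- order(gen$node_time[gen$edge[, 1]], decreasing = TRUE)
  for (e in ord) {
    p <- gen$edge[e, 1]; ch <- gen$edge[e, 2]
    carried[[ch]] <- c(carried[[p]], edge_mut[[e]])
  }
  seqs <- vapply(seq_len(n), function(i) {
    s <- rep("A", L)
    mu <- carried[[i]]
    if (length(mu)) s[cols[mu]] <- base[mu]
    paste(s, collapse = "")
  }, character(1))
  names(seqs) <- gen$tip_label
  seqs
}
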