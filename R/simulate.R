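# Synthetic assembly and sequencing simulator. This is first-class package
# functionality: it emulates the phenomena the QC pipeline measures
# (truncated assemblies, per-unit mutations, pooled-library sampling,
# nanopore-style read noise) with a fully seeded generative model, so the
# pipeline can be exercised and calibrated without any sequencing data.

#' Simulation parameters
#'
#' @param n_molecules Number of assembled molecules to emit.
#' @param junction_failure_prob Per-junction probability `q` that ligation
#'   stops at that junction. A `k`-unit design has `k - 1` internal junctions,
#'   so the full-length fraction is `(1 - q)^(k - 1)` and a failure at
#'   junction `i` leaves an `i`-unit truncated insert.
#' @param deleterious_mutation_prob Per-unit probability of planting one
#'   mutation inside the unit's U6 promoter, spacer or scaffold (the regions
#'   where a mutation can break the guide).
#' @param tail_mutation_prob Per-unit probability of planting one
#'   inconsequential mutation inside the unit's primer-tail regions.
#' @param sub_indel_ratio Proportion of planted mutations (and read errors)
#'   that are substitutions; the remainder are 1-nt insertions or deletions in
#'   equal parts.
#' @param read_error_rate Per-base sequencing error probability.
#' @param revcomp_prob Probability a read is emitted reverse-complemented.
#' @param incomplete_prob Probability a read is emitted with one vector flank
#'   missing (an incomplete plasmid read, which the QC pipeline must discard).
#' @param unit_count_probs Optional explicit probability vector over unit
#'   counts `1..k`; when supplied it replaces the per-junction truncation
#'   model (useful for planting an exact unit-count histogram).
#' @param seed Integer seed; fully determines all simulator output.
#' @return A `sim_params` object.
#' @export
sim_params <- function(n_molecules = 1000L, junction_failure_prob = 0,
                       deleterious_mutation_prob = 0, tail_mutation_prob = 0,
                       sub_indel_ratio = 0.5, read_error_rate = 0,
                       revcomp_prob = 0.5, incomplete_prob = 0,
                       unit_count_probs = NULL, seed = 1L) {
  probs <- c(junction_failure_prob, deleterious_mutation_prob,
             tail_mutation_prob, sub_indel_ratio, read_error_rate,
             revcomp_prob, incomplete_prob, unit_count_probs)
  if (any(probs < 0 | probs > 1)) {
    abort("all probabilities must lie in [0, 1]",
          class = "guidearray_validation_error")
  }
  structure(
    list(n_molecules = as.integer(n_molecules),
         junction_failure_prob = junction_failure_prob,
         deleterious_mutation_prob = deleterious_mutation_prob,
         tail_mutation_prob = tail_mutation_prob,
         sub_indel_ratio = sub_indel_ratio,
         read_error_rate = read_error_rate,
         revcomp_prob = revcomp_prob,
         incomplete_prob = incomplete_prob,
         unit_count_probs = unit_count_probs,
         seed = as.integer(seed)),
    class = "sim_params"
  )
}

# mutate one sequence in place; events is a tibble with ref_position (0-based,
# valid in the unmutated sequence), kind. Applied right to left.
.apply_mutations <- function(seq, events) {
  if (nrow(events) == 0) return(seq)
  events <- events[order(-events$ref_position), ]
  for (i in seq_len(nrow(events))) {
    pos <- events$ref_position[i] + 1L   # 1-based
    kind <- events$kind[i]
    if (kind == "substitution") {
      old <- substr(seq, pos, pos)
      substr(seq, pos, pos) <- sample(setdiff(DNA_BASES, old), 1L)
    } else if (kind == "deletion") {
      seq <- paste0(substr(seq, 1L, pos - 1L), substr(seq, pos + 1L, nchar(seq)))
    } else {
      seq <- paste0(substr(seq, 1L, pos - 1L), sample(DNA_BASES, 1L),
                    substr(seq, pos, nchar(seq)))
    }
  }
  seq
}

.draw_kind <- function(n, sub_ratio) {
  kind <- ifelse(runif(n) < sub_ratio, "substitution",
                 ifelse(runif(n) < 0.5, "insertion", "deletion"))
  kind
}

#' Simulate assembled array molecules
#'
#' Emits `n_molecules` insert sequences from an array design under the
#' truncation and mutation model of [sim_params()], together with the ground
#' truth of everything planted. For a pooled-library design, each present
#' position draws its spacer independently from that position's pool weights.
#'
#' @param design An `array_design`.
#' @param params A `sim_params` object.
#' @return A `gg_sim` object with elements `molecules` (tibble: `molecule_id`,
#'   `n_units`, `sequence`), `truth_units` (tibble: `molecule_id`, `position`,
#'   `name` — the spacer identity drawn at each present position) and
#'   `truth_mutations` (tibble: `molecule_id`, `unit`, `region`, `kind`,
#'   `ref_position`).
#' @export
simulate_molecules <- function(design, params) {
  stopifnot(inherits(design, "array_design"), inherits(params, "sim_params"))
  set.seed(.subseeds(params$seed, 1L)[1])
  n <- params$n_molecules
  k <- design$k
  enzyme <- design$fixtures$enzyme
  ohl <- enzyme$overhang_len
  u6_len <- nchar(design$fixtures$u6_promoter)
  sc_len <- nchar(design$fixtures$scaffold_terminator)
  core_len <- u6_len + 20L + sc_len
  anneal <- design$params$anneal_len
  oh <- unclass(design$overhang_set)

  # unit counts
  q <- params$junction_failure_prob
  if (!is.null(params$unit_count_probs)) {
    pvec <- params$unit_count_probs
    if (length(pvec) != k) {
      abort("unit_count_probs must have length k",
            class = "guidearray_validation_error")
    }
    n_units <- sample.int(k, n, replace = TRUE, prob = pvec)
  } else if (q <= 0 || k == 1L) {
    n_units <- rep(k, n)
  } else {
    n_units <- pmin(stats::rgeom(n, q) + 1L, k)
  }

  # per-position member draws (drawn for all k positions, recorded for
  # present positions only)
  pools <- design$pools
  member_idx <- matrix(1L, nrow = n, ncol = k)
  for (p in seq_len(k)) {
    m <- nrow(pools[[p]])
    if (m > 1L) {
      member_idx[, p] <- sample.int(m, n, replace = TRUE,
                                    prob = pools[[p]]$weight)
    }
  }

  u6 <- design$fixtures$u6_promoter
  sc <- design$fixtures$scaffold_terminator
  # segment for (position, member): core + right overhang
  segs <- lapply(seq_len(k), function(p) {
    paste0(u6, toupper(pools[[p]]$spacer), sc, oh[p + 1L])
  })
  pieces <- lapply(seq_len(k), function(p) {
    ifelse(n_units >= p, segs[[p]][member_idx[, p]], "")
  })
  seq0 <- do.call(paste0, c(list(rep(oh[1], n)), pieces))

  # mutation planting: at most one deleterious and one tail event per unit
  b <- ohl + (seq_len(k) - 1L) * (core_len + ohl)    # core starts
  del_hit <- matrix(rbinom(n * k, 1L, params$deleterious_mutation_prob),
                    nrow = n) == 1L
  tail_hit <- matrix(rbinom(n * k, 1L, params$tail_mutation_prob),
                     nrow = n) == 1L
  present <- outer(n_units, seq_len(k), `>=`)
  del_hit <- del_hit & present
  tail_hit <- tail_hit & present

  events <- list()
  if (any(del_hit) || any(tail_hit)) {
    for (i in which(rowSums(del_hit) + rowSums(tail_hit) > 0)) {
      ev <- list()
      for (p in which(del_hit[i, ])) {
        # uniform over the unit's deleterious span [b + anneal, b + core - anneal)
        pos <- b[p] + anneal + sample.int(core_len - 2L * anneal, 1L) - 1L
        region <- if (pos < b[p] + u6_len) "u6_promoter"
                  else if (pos < b[p] + u6_len + 20L) "spacer"
                  else "scaffold"
        ev[[length(ev) + 1L]] <- tibble(
          molecule_id = i, unit = p, region = region,
          kind = .draw_kind(1L, params$sub_indel_ratio), ref_position = pos)
      }
      for (p in which(tail_hit[i, ])) {
        left <- if (p == 1L) 0L else b[p] - ohl
        left_span <- seq.int(left, b[p] + anneal - 1L)
        right_end <- if (p == k) b[p] + core_len + ohl else b[p] + core_len
        right_span <- seq.int(b[p] + core_len - anneal, right_end - 1L)
        span <- c(left_span, right_span)
        pos <- span[sample.int(length(span), 1L)]
        ev[[length(ev) + 1L]] <- tibble(
          molecule_id = i, unit = p, region = "primer_tail",
          kind = .draw_kind(1L, params$sub_indel_ratio), ref_position = pos)
      }
      events[[length(events) + 1L]] <- list_rbind(ev)
    }
  }
  truth_mutations <- if (length(events)) list_rbind(events) else {
    tibble(molecule_id = integer(0), unit = integer(0), region = character(0),
           kind = character(0), ref_position = integer(0))
  }

  if (nrow(truth_mutations) > 0) {
    for (i in unique(truth_mutations$molecule_id)) {
      seq0[i] <- .apply_mutations(seq0[i],
                                  truth_mutations[truth_mutations$molecule_id == i, ])
    }
  }

  mol_rep <- rep.int(seq_len(n), n_units)
  pos_rep <- sequence(n_units)
  name_mat <- do.call(cbind, lapply(seq_len(k), function(p) {
    pools[[p]]$name[member_idx[, p]]
  }))
  truth_units <- tibble(
    molecule_id = mol_rep,
    position = pos_rep,
    name = name_mat[cbind(mol_rep, pos_rep)]
  )

  structure(
    list(molecules = tibble(molecule_id = seq_len(n), n_units = n_units,
                            sequence = seq0),
         truth_units = truth_units,
         truth_mutations = truth_mutations,
         k = k, params = params),
    class = "gg_sim"
  )
}

#' @rdname simulate_molecules
#' @details `simulate_library_molecules()` is the pooled-library entry point;
#'   each present position draws its member from the position's pool weights.
#'   With single-member pools it reduces exactly to [simulate_molecules()].
#' @export
simulate_library_molecules <- function(design, params) {
  stopifnot(inherits(design, "array_design"))
  simulate_molecules(design, params)
}

#' @export
print.gg_sim <- function(x, ...) {
  cat(sprintf("<simulated assembly: %d molecules, k = %d>\n",
              nrow(x$molecules), x$k))
  cat(sprintf("  full length: %.1f%%; planted mutations: %d\n",
              100 * mean(x$molecules$n_units == x$k),
              nrow(x$truth_mutations)))
  invisible(x)
}

#' Simulate nanopore-style plasmid reads
#'
#' Wraps each molecule in the vector flanks (emulating whole-plasmid reads),
#' then applies per-base sequencing errors, optional reverse-complementing,
#' and optional flank loss (incomplete reads).
#'
#' @param molecules A `gg_sim` object or a character vector of molecule
#'   sequences.
#' @param fixtures A `gg_fixtures` object supplying the vector flanks.
#' @param params A `sim_params` object (`read_error_rate`, `revcomp_prob`,
#'   `incomplete_prob`, `sub_indel_ratio`, `seed` are used).
#' @return A tibble with columns `read_id`, `molecule_id`, `strand`,
#'   `sequence`. Reads are index-aligned with the molecules.
#' @export
simulate_reads <- function(molecules, fixtures, params) {
  stopifnot(inherits(fixtures, "gg_fixtures"), inherits(params, "sim_params"))
  mols <- if (inherits(molecules, "gg_sim")) molecules$molecules$sequence
          else as.character(molecules)
  set.seed(.subseeds(params$seed, 2L)[2])
  n <- length(mols)
  fu <- fixtures$vector_flank_up
  fd <- fixtures$vector_flank_down
  raw <- paste0(fu, mols, fd)
  incomplete <- runif(n) < params$incomplete_prob
  drop_up <- runif(n) < 0.5
  raw[incomplete & drop_up] <- paste0(mols[incomplete & drop_up], fd)
  raw[incomplete & !drop_up] <- paste0(fu, mols[incomplete & !drop_up])

  e <- params$read_error_rate
  if (e > 0) {
    lens <- nchar(raw)
    n_err <- rbinom(n, lens, e)
    for (i in which(n_err > 0)) {
      pos <- sort(sample.int(lens[i], n_err[i]), decreasing = TRUE)
      kind <- .draw_kind(n_err[i], params$sub_indel_ratio)
      chars <- strsplit(raw[i], "")[[1]]
      for (j in seq_along(pos)) {
        if (kind[j] == "substitution") {
          chars[pos[j]] <- sample(setdiff(DNA_BASES, chars[pos[j]]), 1L)
        } else if (kind[j] == "deletion") {
          chars <- chars[-pos[j]]
        } else {
          chars <- append(chars, sample(DNA_BASES, 1L), after = pos[j] - 1L)
        }
      }
      raw[i] <- paste(chars, collapse = "")
    }
  }

  flip <- runif(n) < params$revcomp_prob
  if (any(flip)) raw[flip] <- revcomp(raw[flip])
  tibble(
    read_id = sprintf("read_%05d", seq_len(n)),
    molecule_id = seq_len(n),
    strand = ifelse(flip, "-", "+"),
    sequence = raw
  )
}
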