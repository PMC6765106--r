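# Evaluate expr with a temporary RNG state seeded at `seed`, restoring the
# caller's RNG state afterwards. Simulator outputs are pure functions of
# their seeds and parameters.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

DNA_BASES <- c("A", "C", "G", "T")

#' Deterministic example amplicon sequence
#'
#' A fixed pseudo-random DNA sequence at the scale of a typical long
#' viral-gene amplicon, used as the default simulation seed sequence.
#' The same call always returns the same sequence.
#'
#' @param length Sequence length (default 2600).
#' @return A DNA string.
#' @export
example_amplicon <- function(length = 2600L) {
  with_seed(104729L, paste0(sample(DNA_BASES, length, replace = TRUE),
                            collapse = ""))
}

#' Error profile for simulated CCS reads
#'
#' Long-read CCS errors are dominated by indels concentrated in
#' homopolymer regions, with a rate that grows with the run length; the
#' remainder are substitutions. The profile fixes a per-base substitution
#' probability and a per-homopolymer-unit indel probability: a run of
#' length r >= 2 suffers a one-unit length change (+1 or -1 with equal
#' probability) with probability `min(1, indel_base_rate * r)`; isolated
#' bases (runs of length 1) receive no indels. Quality
#' strings are constant-Q per read, with Q chosen so the quality-implied
#' expected error count matches the profile's expected errors.
#'
#' @param sub_rate Per-base substitution probability, in `[0, 0.2]`.
#' @param indel_base_rate Per-homopolymer-unit indel probability, in
#'   `[0, 0.2]`.
#' @return A list of class `error_profile`.
#' @export
error_profile <- function(sub_rate = 0.002, indel_base_rate = 0.008) {
  stopifnot(sub_rate >= 0, sub_rate <= 0.2,
            indel_base_rate >= 0, indel_base_rate <= 0.2)
  structure(list(sub_rate = sub_rate, indel_base_rate = indel_base_rate),
            class = "error_profile")
}

# Expected errors per base of a template under a profile (substitutions
# plus one candidate indel event per homopolymer run of length >= 2).
profile_error_rate <- function(template_runs, profile) {
  L <- sum(template_runs$lengths)
  runs <- template_runs$lengths[template_runs$lengths >= 2L]
  indels <- sum(pmin(1, profile$indel_base_rate * runs))
  profile$sub_rate + indels / L
}

template_runs <- function(sequence) {
  rle(strsplit(sequence, "", fixed = TRUE)[[1L]])
}

#' Generate a population of closely related templates
#'
#' Derives `n_templates` variants from a seed sequence, each carrying the
#' stated number of random substitutions and one-base indels at uniform
#' positions, rejection-resampled until all pairwise edit distances reach
#' `min_pairwise_distance`. Frequencies are drawn from a uniform
#' distribution and normalised. Fully reproducible from `rng_seed`.
#'
#' @param seed_sequence The ancestral sequence (at least 500 bp).
#' @param n_templates Number of templates.
#' @param subs_per_template Substitutions per template.
#' @param indels_per_template One-base insertions/deletions per template.
#' @param min_pairwise_distance Minimum pairwise edit distance enforced
#'   between all templates.
#' @param rng_seed Integer seed.
#' @return A [weighted_population()].
#' @export
generate_templates <- function(seed_sequence, n_templates,
                               subs_per_template = 5L,
                               indels_per_template = 0L,
                               min_pairwise_distance = 1L,
                               rng_seed = 1L) {
  stopifnot(nchar(seed_sequence) >= 500, n_templates >= 1,
            subs_per_template >= 0, indels_per_template >= 0)
  with_seed(rng_seed, {
    for (attempt in seq_len(1000L)) {
      seqs <- vapply(seq_len(n_templates), function(i) {
        mutate_sequence(seed_sequence, subs_per_template, indels_per_template)
      }, character(1))
      if (n_templates == 1L) break
      D <- edit_distance_matrix(seqs, seqs)
      if (min(D[upper.tri(D)]) >= min_pairwise_distance &&
          !anyDuplicated(seqs)) {
        break
      }
      if (attempt == 1000L) {
        stop("could not generate templates at the requested minimum ",
             "pairwise distance; relax the constraint")
      }
    }
    freq <- stats::runif(n_templates)
    weighted_population(seqs, freq / sum(freq))
  })
}

# Apply a fixed number of random substitutions and one-base indels to a
# sequence (uniform positions; substitutions always change the base).
mutate_sequence <- function(sequence, n_subs, n_indels) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  if (n_subs > 0L) {
    pos <- sample.int(length(chars), n_subs)
    cur <- match(chars[pos], DNA_BASES)
    off <- sample.int(3L, n_subs, replace = TRUE)
    chars[pos] <- DNA_BASES[(cur - 1L + off) %% 4L + 1L]
  }
  if (n_indels > 0L) {
    for (e in seq_len(n_indels)) {
      if (stats::runif(1) < 0.5 && length(chars) > 1L) {
        chars <- chars[-sample.int(length(chars), 1L)]
      } else {
        at <- sample.int(length(chars) + 1L, 1L)
        chars <- append(chars, sample(DNA_BASES, 1L), after = at - 1L)
      }
    }
  }
  paste0(chars, collapse = "")
}

# Simulate one noisy read from cached template runs. Indels are confined
# to homopolymer runs (length >= 2), where long-read CCS indel errors
# concentrate; isolated bases only ever suffer substitutions.
noisy_read <- function(runs, profile) {
  lens <- runs$lengths
  hit <- lens >= 2L &
    stats::runif(length(lens)) < pmin(1, profile$indel_base_rate * lens)
  if (any(hit)) {
    delta <- ifelse(stats::runif(sum(hit)) < 0.5, -1L, 1L)
    lens[hit] <- pmax(0L, lens[hit] + delta)
  }
  chars <- rep(runs$values, lens)
  sub <- which(stats::runif(length(chars)) < profile$sub_rate)
  if (length(sub) > 0L) {
    cur <- match(chars[sub], DNA_BASES)
    off <- sample.int(3L, length(sub), replace = TRUE)
    chars[sub] <- DNA_BASES[(cur - 1L + off) %% 4L + 1L]
  }
  paste0(chars, collapse = "")
}

phred_for_rate <- function(p) {
  if (p <= 0) return(93L)
  min(93L, max(2L, as.integer(round(-10 * log10(p)))))
}

# Workhorse: one read per entry of `origins` (template indices), sequential
# RNG consumption so results are reproducible read by read.
sim_reads_from_origins <- function(population, origins, profile) {
  runs <- lapply(population$sequences, template_runs)
  quals <- vapply(runs, function(r) {
    phred_for_rate(profile_error_rate(r, profile))
  }, integer(1))
  seqs <- character(length(origins))
  for (i in seq_along(origins)) {
    seqs[i] <- noisy_read(runs[[origins[i]]], profile)
  }
  qual_list <- lapply(seq_along(origins), function(i) {
    rep(quals[origins[i]], nchar(seqs[i]))
  })
  read_set(sprintf("read_%d", seq_along(origins)), seqs, qual_list)
}

#' Simulate noisy CCS-like reads from a template population
#'
#' Each read samples its template by frequency, then acquires
#' substitutions per base and homopolymer-length indels per run according
#' to the [error_profile()]. Quality strings are constant-Q per read,
#' matched to the profile's expected per-base error rate for the
#' originating template, so quality-derived expected errors agree with the
#' simulated error process. Reproducible from `rng_seed`.
#'
#' @param truth A [weighted_population()] of templates.
#' @param n_reads Number of reads.
#' @param profile An [error_profile()].
#' @param rng_seed Integer seed.
#' @return A list with `reads` (a `read_set`) and `ground_truth` (list
#'   with `templates`, a [weighted_population()] whose frequencies are the
#'   realised origin proportions of this simulated dataset, and
#'   `read_origins`, the template index of every read).
#' @export
simulate_reads <- function(truth, n_reads, profile, rng_seed = 1L) {
  stopifnot(n_reads >= 1)
  truth <- as_weighted_population(truth)
  with_seed(rng_seed, {
    origins <- sample.int(length(truth$sequences), n_reads, replace = TRUE,
                          prob = truth$frequencies)
    reads <- sim_reads_from_origins(truth, origins, profile)
    gt_freq <- tabulate(origins, nbins = length(truth$sequences)) / n_reads
    list(
      reads = reads,
      ground_truth = list(
        templates = structure(list(sequences = truth$sequences,
                                   frequencies = gt_freq),
                              class = "weighted_population"),
        read_origins = origins
      )
    )
  })
}

#' Packaged simulation fixtures for the two denoising regimes
#'
#' Canned parameterisations of the simulator that emulate the study
#' conditions under which the two denoisers are expected to operate:
#'
#' * `"low_error"`: 20 templates at the 2.6 kb scale (pairwise edit
#'   distance at least 3), 100 reads each, and a per-base error rate of
#'   3.7e-4 (80% homopolymer indels / 20% substitutions), the regime of a
#'   high-quality 2.6 kb CCS run where roughly 38% of reads are error
#'   free -- fast-denoiser territory.
#' * `"high_error"`: 10 templates at percent-scale divergence (60
#'   substitutions each from the common ancestor, pairwise at least 30
#'   edits), 200 reads each, 1% indel-heavy error -- essentially no
#'   error-free reads, so only clustering plus consensus can recover the
#'   templates. At this error level reads sit about 0.008 scaled kmer
#'   distance from their own template, so the coarse clustering radius
#'   must exceed roughly twice that; see [rad_config()].
#' * `"single_base_pair"`: 2 templates differing by exactly one
#'   substitution, 500 reads each, low error -- the hardest
#'   discrimination case. The variant site is placed in
#'   homopolymer-free kmer context: a substitution whose whole kmer
#'   neighbourhood is homopolymeric reads as a homopolymer length error
#'   to any kmer method, so such positions are out of scope for this
#'   fixture.
#'
#' Reads are allocated to templates in exact equal proportion (template
#' frequencies are uniform) and shuffled; the ground-truth frequencies
#' are therefore exactly uniform.
#'
#' @param kind One of `"low_error"`, `"high_error"`,
#'   `"single_base_pair"`.
#' @param rng_seed Integer seed; the whole fixture is a pure function of
#'   it.
#' @return As [simulate_reads()]: list with `reads` and `ground_truth`.
#' @export
mvc_fixture <- function(kind = c("low_error", "high_error",
                                 "single_base_pair"),
                        rng_seed = 1L) {
  kind <- match.arg(kind)
  base_seq <- example_amplicon(2600L)
  if (kind == "single_base_pair") {
    pop <- with_seed(rng_seed, {
      chars <- strsplit(base_seq, "", fixed = TRUE)[[1L]]
      # restrict the variant to positions whose 6-mer neighbourhood is
      # homopolymer free: a substitution whose entire kmer context is
      # homopolymeric is indistinguishable from a homopolymer length
      # error by kmer methods, and so outside this fixture's scope
      candidates <- Filter(function(p) {
        win <- chars[(p - 6L):(p + 6L)]
        !any(win[-1L] == win[-length(win)])
      }, seq.int(101L, nchar(base_seq) - 100L))
      pos <- candidates[sample.int(length(candidates), 1L)]
      repl <- setdiff(DNA_BASES, chars[(pos - 1L):(pos + 1L)])
      chars[pos] <- repl[sample.int(length(repl), 1L)]
      weighted_population(c(base_seq, paste0(chars, collapse = "")),
                          c(0.5, 0.5))
    })
    coverage <- 500L
    profile <- error_profile(sub_rate = 8e-5, indel_base_rate = 7.3e-4)
  } else if (kind == "low_error") {
    pop <- generate_templates(base_seq, n_templates = 20L,
                              subs_per_template = 5L,
                              indels_per_template = 0L,
                              min_pairwise_distance = 3L,
                              rng_seed = rng_seed)
    pop$frequencies <- rep(1 / 20, 20L)
    coverage <- 100L
    profile <- error_profile(sub_rate = 7.4e-5, indel_base_rate = 6.8e-4)
  } else {
    pop <- generate_templates(base_seq, n_templates = 10L,
                              subs_per_template = 60L,
                              indels_per_template = 0L,
                              min_pairwise_distance = 30L,
                              rng_seed = rng_seed)
    pop$frequencies <- rep(1 / 10, 10L)
    coverage <- 200L
    profile <- error_profile(sub_rate = 0.002, indel_base_rate = 0.018)
  }
  n_t <- length(pop$sequences)
  with_seed(rng_seed + 1L, {
    origins <- sample(rep(seq_len(n_t), each = coverage))
    reads <- sim_reads_from_origins(pop, origins, profile)
    list(
      reads = reads,
      ground_truth = list(
        templates = structure(list(sequences = pop$sequences,
                                   frequencies = rep(1 / n_t, n_t)),
                              class = "weighted_population"),
        read_origins = origins
      )
    )
  })
}

#' Write reads to a FASTQ file
#'
#' Phred+33 output, four lines per record; the inverse of [read_fastq()].
#'
#' @param reads A `read_set`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(reads, path) {
  qual_strings <- vapply(reads$quality, function(q) {
    intToUtf8(q + 33L)
  }, character(1))
  lines <- as.vector(rbind(paste0("@", reads$id),
                           reads$sequence,
                           rep("+", nrow(reads)),
                           qual_strings))
  writeLines(lines, path)
  invisible(path)
}
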