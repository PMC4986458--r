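#' Configuration for the allo-octoploid cross simulator
#'
#' The simulator embodies a two-step allopolyploid history: a vesca-like
#' diploid and an iinumae-like diploid formed an allotetraploid
#' (Av + Bi), which then merged with an iinumae-like autotetraploid
#' (B1 + B2) to produce an octoploid with four disomically inherited
#' subgenomes. Substitutions are placed independently along each branch of
#' the fixed topology `((vesca, Av), (iinumae, Bi), B1, B2)` with a distant
#' outgroup, introgression is modeled as wholesale tract replacement of an
#' iinumae-like subgenome by vesca-lineage sequence, and transpositions are
#' copy-and-paste duplications of a donor segment into another chromosome.
#'
#' Rates are per-site substitution probabilities per branch; all defaults
#' are in units of substitutions/site. `depth` is the expected per-site
#' read depth per individual over a capture target.
#'
#' @param seed RNG seed for the whole experiment.
#' @param n_chromosomes,chromosome_length genome shape (default 7 x 1 Mb).
#' @param targets_per_chromosome evenly spaced capture targets (default 300).
#' @param n_progeny F1 progeny per cross (default 48).
#' @param depth expected per-individual depth at a target (default 80).
#' @param error_rate per-base sequencing error probability (default 0.002).
#' @param read_length read length in bp (default 100).
#' @param recomb_per_chromosome expected crossovers per gamete per
#'   chromosome (default 1.5).
#' @param het_rate per-site probability of an injected parental
#'   heterozygous site within each subgenome copy (default 0.002); these
#'   are the planted single-subgenome LG SNP candidates.
#' @param rates named list of branch substitution rates: `outgroup`,
#'   `vesca_clade` (stem to the vesca-like pair), `b_clade` (stem to the
#'   iinumae-like radiation), `bi_clade` (stem to the iinumae/Bi pair) and
#'   `tip` (terminal branches; B1 gets `tip_b1`, slightly larger, so the
#'   B1/B2 divergence criterion has signal).
#' @param n_tracts,tract_length planted introgression tracts (default 8
#'   tracts of 30 kb each), placed on iinumae-like subgenomes.
#' @param tract_direction `"B_to_vesca"` (default) or `"bidirectional"`.
#' @param n_transpositions,transposition_length planted copy-and-paste
#'   duplications spanning a targeted region (default 2 of 2 kb).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_chromosomes = 7,
                       chromosome_length = 1e6,
                       targets_per_chromosome = 300,
                       n_progeny = 48,
                       depth = 80,
                       error_rate = 0.002,
                       read_length = 100,
                       recomb_per_chromosome = 1.5,
                       het_rate = 0.002,
                       rates = list(outgroup = 0.04, vesca_clade = 0.012,
                                    b_clade = 0.010, bi_clade = 0.008,
                                    tip = 0.005, tip_b1 = 0.010),
                       n_tracts = 8,
                       tract_length = 30000,
                       tract_direction = c("B_to_vesca", "bidirectional"),
                       n_transpositions = 2,
                       transposition_length = 2000) {
  tract_direction <- match.arg(tract_direction)
  stopifnot(all(unlist(rates) >= 0), all(unlist(rates) < 0.5),
            n_progeny >= 16)
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

# ---- sparse variant maps ---------------------------------------------------

.vm <- function(pos = integer(0), base = character(0)) {
  o <- order(pos)
  list(pos = as.integer(pos[o]), base = base[o])
}

.vm_base_at <- function(vm, pos, ref_chrom) {
  i <- match(pos, vm$pos)
  out <- substring(ref_chrom, pos, pos)
  out[!is.na(i)] <- vm$base[i[!is.na(i)]]
  out
}

# override wins at shared positions
.vm_merge <- function(base_vm, override) {
  keep <- !(base_vm$pos %in% override$pos)
  .vm(c(base_vm$pos[keep], override$pos),
      c(base_vm$base[keep], override$base))
}

.vm_window <- function(vm, s, e) {
  sel <- vm$pos >= s & vm$pos <= e
  .vm(vm$pos[sel], vm$base[sel])
}

# replace vm content inside [s, e] with donor's content there
.vm_replace_window <- function(vm, donor, s, e) {
  keep <- vm$pos < s | vm$pos > e
  dw <- .vm_window(donor, s, e)
  .vm(c(vm$pos[keep], dw$pos), c(vm$base[keep], dw$base))
}

# mutate along a branch: rate per site over length L
.vm_mutate <- function(vm, ref_chrom, L, rate) {
  k <- stats::rbinom(1L, L, rate)
  if (k == 0L) return(vm)
  pos <- sample.int(L, k)
  cur <- .vm_base_at(vm, pos, ref_chrom)
  new <- vapply(cur, function(b) sample(setdiff(c("A", "C", "G", "T"), b),
                                        1L), character(1))
  .vm_merge(vm, .vm(pos, unname(new)))
}

.random_chrom <- function(L) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

# ---- lineages --------------------------------------------------------------

#' Simulate diploid ancestors, subgenome haplotypes and the outgroup
#'
#' Generates a random reference per chromosome, then drops substitutions
#' along each branch of the fixed topology to obtain the outgroup, the
#' vesca-like and iinumae-like diploids and the four subgenome base
#' sequences, and finally plants the configured introgression tracts
#' (tract sequence copied from the vesca lineage into an iinumae-like
#' subgenome, or the reverse for bidirectional configurations). Call
#' within an active seed context or via [simulate_octoploid_experiment()].
#'
#' @param config a [sim_config()].
#' @return list with `reference` (character string per chromosome),
#'   `chrom_names`, `taxa` (variant maps per chromosome for `vesca`,
#'   `iinumae`, `outgroup`), `subgenomes` (`Av`, `Bi`, `B1`, `B2`) and
#'   `tracts` (data.frame `subgenome`, `chrom`, `start`, `end`,
#'   `direction`).
#' @export
simulate_lineages <- function(config) {
  L <- config$chromosome_length
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  r <- config$rates
  reference <- stats::setNames(
    lapply(chroms, function(ch) .random_chrom(L)), chroms)
  empty <- stats::setNames(lapply(chroms, function(ch) .vm()), chroms)
  mut_all <- function(maps, rate) {
    stats::setNames(lapply(chroms, function(ch) {
      .vm_mutate(maps[[ch]], reference[[ch]], L, rate)
    }), chroms)
  }
  root <- empty
  outgroup <- mut_all(root, r$outgroup)
  vesca_anc <- mut_all(root, r$vesca_clade)
  vesca <- mut_all(vesca_anc, r$tip)
  Av <- mut_all(vesca_anc, r$tip)
  b_anc <- mut_all(root, r$b_clade)
  bi_anc <- mut_all(b_anc, r$bi_clade)
  iinumae <- mut_all(bi_anc, r$tip)
  Bi <- mut_all(bi_anc, r$tip)
  B1 <- mut_all(b_anc, r$tip_b1)
  B2 <- mut_all(b_anc, r$tip)
  subg <- list(Av = Av, Bi = Bi, B1 = B1, B2 = B2)
  # plant tracts
  tracts <- NULL
  if (config$n_tracts > 0) {
    b_names <- c("Bi", "B1", "B2")
    for (t in seq_len(config$n_tracts)) {
      bidirectional <- config$tract_direction == "bidirectional"
      to_vesca <- !bidirectional || stats::runif(1) < 0.5
      sg <- if (to_vesca) sample(b_names, 1L) else "Av"
      ch <- sample(chroms, 1L)
      start <- sample.int(L - config$tract_length, 1L)
      end <- start + config$tract_length - 1L
      donor <- if (to_vesca) vesca[[ch]] else iinumae[[ch]]
      subg[[sg]][[ch]] <- .vm_replace_window(subg[[sg]][[ch]], donor,
                                             start, end)
      tracts <- rbind(tracts, data.frame(
        subgenome = sg, chrom = ch, start = start, end = end,
        direction = if (to_vesca) "to_vesca" else "to_iinumae",
        stringsAsFactors = FALSE))
    }
  }
  list(reference = reference, chrom_names = chroms,
       taxa = list(vesca = vesca, iinumae = iinumae, outgroup = outgroup),
       subgenomes = subg, tracts = tracts)
}

# ---- parents and cross -----------------------------------------------------

#' Phase octoploid parents with injected single-subgenome heterozygosity
#'
#' Each parent carries two haplotypes per subgenome per chromosome. Both
#' start as the subgenome base sequence; heterozygosity is injected at
#' rate `het_rate` by giving one randomly chosen haplotype a new base.
#' These injected sites are the planted LG SNP candidates (minor-allele
#' frequency 1/8 in the parent's capture reads).
#'
#' @param lineages output of [simulate_lineages()].
#' @param config a [sim_config()].
#' @return list with `parents` (nested list parent -> subgenome ->
#'   chromosome -> `h1`/`h2` variant maps) and `het_truth` (data.frame
#'   `parent`, `subgenome`, `chrom`, `pos`, `hap`, `base`).
#' @export
simulate_parents <- function(lineages, config) {
  L <- config$chromosome_length
  chroms <- lineages$chrom_names
  parents <- list()
  truth <- NULL
  for (p in c("maternal", "paternal")) {
    parents[[p]] <- list()
    for (sg in names(lineages$subgenomes)) {
      parents[[p]][[sg]] <- list()
      for (ch in chroms) {
        base_vm <- lineages$subgenomes[[sg]][[ch]]
        h <- list(h1 = base_vm, h2 = base_vm)
        k <- stats::rbinom(1L, L, config$het_rate)
        if (k > 0L) {
          pos <- sample.int(L, k)
          cur <- .vm_base_at(base_vm, pos, lineages$reference[[ch]])
          new <- vapply(cur, function(b) {
            sample(setdiff(c("A", "C", "G", "T"), b), 1L)
          }, character(1))
          hap <- sample(c("h1", "h2"), k, replace = TRUE)
          for (hh in c("h1", "h2")) {
            sel <- hap == hh
            if (any(sel)) {
              h[[hh]] <- .vm_merge(h[[hh]], .vm(pos[sel], unname(new[sel])))
            }
          }
          truth <- rbind(truth, data.frame(
            parent = p, subgenome = sg, chrom = ch, pos = pos, hap = hap,
            base = unname(new), stringsAsFactors = FALSE))
        }
        parents[[p]][[sg]][[ch]] <- h
      }
    }
  }
  list(parents = parents, het_truth = truth)
}

# gamete = recombination pattern: sorted crossover breaks + starting hap
.make_gamete <- function(L, recomb) {
  k <- stats::rpois(1L, recomb)
  list(breaks = sort(stats::runif(k, 1, L)),
       start_hap = sample(1:2, 1L))
}

#' Which parental haplotype a gamete carries at a position
#' @param gamete list with `breaks` and `start_hap` (see
#'   [simulate_cross()]).
#' @param pos query position(s).
#' @return integer vector of 1/2.
#' @export
gamete_hap_at <- function(gamete, pos) {
  n_breaks <- vapply(pos, function(p) sum(gamete$breaks < p), integer(1))
  ifelse(n_breaks %% 2L == 0L, gamete$start_hap, 3L - gamete$start_hap)
}

#' Simulate a disomic F1 cross
#'
#' Every progeny inherits, for each subgenome and each chromosome, one
#' recombinant haplotype from each parent (Poisson crossover count,
#' uniform positions). Homeologs never exchange: recombination is strictly
#' within a subgenome.
#'
#' @param config a [sim_config()].
#' @param chrom_names chromosome names.
#' @param subgenome_names subgenome names.
#' @return list of progeny; each progeny is a nested list parent ->
#'   subgenome -> chromosome -> gamete (breaks, start_hap).
#' @export
simulate_cross <- function(config, chrom_names,
                           subgenome_names = c("Av", "Bi", "B1", "B2")) {
  lapply(seq_len(config$n_progeny), function(i) {
    g <- list()
    for (p in c("maternal", "paternal")) {
      g[[p]] <- list()
      for (sg in subgenome_names) {
        g[[p]][[sg]] <- stats::setNames(lapply(chrom_names, function(ch) {
          .make_gamete(config$chromosome_length,
                       config$recomb_per_chromosome)
        }), chrom_names)
      }
    }
    g
  })
}

# gamete haplotype's variant map, assembled piecewise from the parent pair
.gamete_vm <- function(hap_pair, gamete, L) {
  bounds <- c(1, gamete$breaks, L + 1)
  out_pos <- integer(0); out_base <- character(0)
  hap <- gamete$start_hap
  for (s in seq_len(length(bounds) - 1L)) {
    vmw <- .vm_window(hap_pair[[hap]], ceiling(bounds[s]),
                      ceiling(bounds[s + 1L]) - 1L)
    out_pos <- c(out_pos, vmw$pos); out_base <- c(out_base, vmw$base)
    hap <- 3L - hap
  }
  .vm(out_pos, out_base)
}

# ---- transpositions --------------------------------------------------------

#' Plant copy-and-paste transpositions
#'
#' Each event duplicates a donor segment (centred on a capture target) of
#' one subgenome into a different chromosome of the same subgenome. The
#' inserted copy is fixed in both parents (riding both haplotypes at the
#' acceptor site), which inflates capture depth at the donor region; one
#' heterozygous variant is additionally injected into the copy on a single
#' haplotype of one parent, producing an LG SNP that maps to the donor
#' chromosome but segregates with the acceptor chromosome — a detectable
#' interchromosomal rearrangement.
#'
#' @param lineages,config as elsewhere.
#' @param targets data.frame of capture targets (`chrom`, `central`).
#' @return data.frame describing the events: donor/acceptor coordinates,
#'   which parent/haplotype carries the diagnostic het and its position
#'   and base, plus a list-column `vm` with the copy's variant map.
#' @export
simulate_transpositions <- function(lineages, config, targets) {
  n <- config$n_transpositions
  if (n == 0L) {
    return(NULL)
  }
  L <- config$chromosome_length
  half <- floor(config$transposition_length / 2)
  out <- NULL
  vms <- vector("list", n)
  picked <- sample(seq_len(nrow(targets)), n)
  for (i in seq_len(n)) {
    tg <- targets[picked[i], ]
    sg <- sample(c("Av", "Bi", "B1", "B2"), 1L)
    donor_chrom <- tg$chrom
    donor_start <- max(1L, tg$central - half)
    donor_end <- min(L, tg$central + half)
    acceptor_chrom <- sample(setdiff(lineages$chrom_names, donor_chrom), 1L)
    acceptor_pos <- sample.int(L, 1L)
    vm <- .vm_window(lineages$subgenomes[[sg]][[donor_chrom]],
                     donor_start, donor_end)
    # diagnostic heterozygous variant inside the copy, near the target
    het_pos <- tg$central + sample(c(-15:-5, 5:15), 1L)
    cur <- .vm_base_at(vm, het_pos, lineages$reference[[donor_chrom]])
    het_base <- sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
    out <- rbind(out, data.frame(
      event = i, subgenome = sg, donor_chrom = donor_chrom,
      donor_start = donor_start, donor_end = donor_end,
      acceptor_chrom = acceptor_chrom, acceptor_pos = acceptor_pos,
      het_parent = sample(c("maternal", "paternal"), 1L),
      het_hap = sample(1:2, 1L), het_pos = het_pos, het_base = het_base,
      stringsAsFactors = FALSE))
    vms[[i]] <- vm
  }
  out$vm <- vms
  out
}

# ---- individuals as copy sets ----------------------------------------------

# A "copy" is one sequence copy an individual carries that maps to the
# reference: chrom, start, end (full chromosome for base haplotypes,
# the donor interval for transposed copies) and a variant map.
.copy <- function(chrom, start, end, vm) {
  list(chrom = chrom, start = start, end = end, vm = vm)
}

#' Expand parents and progeny into per-individual sequence-copy sets
#'
#' @param lineages,parents,progeny,transpositions,config simulator
#'   components.
#' @return named list of individuals (`maternal`, `paternal`, `F1_1`,
#'   ...); each is a list of copies plus attribute `base_copies` (8 for
#'   octoploids).
#' @export
build_individuals <- function(lineages, parents, progeny, transpositions,
                              config) {
  L <- config$chromosome_length
  chroms <- lineages$chrom_names
  tp_copy <- function(tp_row, carries_het) {
    vm <- tp_row$vm[[1L]]
    if (carries_het) {
      vm <- .vm_merge(vm, .vm(tp_row$het_pos, tp_row$het_base))
    }
    .copy(tp_row$donor_chrom, tp_row$donor_start, tp_row$donor_end, vm)
  }
  inds <- list()
  for (p in c("maternal", "paternal")) {
    cp <- list()
    for (sg in names(parents[[p]])) {
      for (ch in chroms) {
        hp <- parents[[p]][[sg]][[ch]]
        cp[[length(cp) + 1L]] <- .copy(ch, 1L, L, hp$h1)
        cp[[length(cp) + 1L]] <- .copy(ch, 1L, L, hp$h2)
      }
    }
    if (!is.null(transpositions)) {
      for (i in seq_len(nrow(transpositions))) {
        tp <- transpositions[i, ]
        for (hap in 1:2) {
          cp[[length(cp) + 1L]] <- tp_copy(
            tp, tp$het_parent == p & tp$het_hap == hap)
        }
      }
    }
    attr(cp, "base_copies") <- 8L
    inds[[p]] <- cp
  }
  for (k in seq_along(progeny)) {
    cp <- list()
    for (p in c("maternal", "paternal")) {
      for (sg in names(parents[[p]])) {
        for (ch in chroms) {
          gm <- progeny[[k]][[p]][[sg]][[ch]]
          cp[[length(cp) + 1L]] <- .copy(
            ch, 1L, L, .gamete_vm(parents[[p]][[sg]][[ch]], gm, L))
        }
      }
      if (!is.null(transpositions)) {
        for (i in seq_len(nrow(transpositions))) {
          tp <- transpositions[i, ]
          gm <- progeny[[k]][[p]][[tp$subgenome]][[tp$acceptor_chrom]]
          hap <- gamete_hap_at(gm, tp$acceptor_pos)
          cp[[length(cp) + 1L]] <- tp_copy(
            tp, tp$het_parent == p & tp$het_hap == hap)
        }
      }
    }
    attr(cp, "base_copies") <- 8L
    inds[[paste0("F1_", k)]] <- cp
  }
  # diploid vesca-like reference individual for depth normalisation
  cp <- list()
  for (ch in chroms) {
    cp[[length(cp) + 1L]] <- .copy(ch, 1L, L, lineages$taxa$vesca[[ch]])
    cp[[length(cp) + 1L]] <- .copy(ch, 1L, L, lineages$taxa$vesca[[ch]])
  }
  attr(cp, "base_copies") <- 2L
  inds[["diploid_ref"]] <- cp
  inds
}

# ---- capture simulation ----------------------------------------------------

#' Candidate variant sites within capture windows
#'
#' Union of all positions at which any taxon, subgenome haplotype or
#' transposed copy differs from the reference, restricted to windows of
#' one read length around the target centres (the only places capture
#' reads reach).
#'
#' @param lineages,parents,transpositions simulator components.
#' @param targets data.frame with `chrom`, `central`.
#' @param read_length window half-width driver.
#' @return data.frame `chrom`, `pos`, `ref` sorted by position.
#' @export
candidate_sites <- function(lineages, parents, transpositions, targets,
                            read_length = 100) {
  out <- NULL
  for (ch in lineages$chrom_names) {
    pos <- integer(0)
    for (tx in lineages$taxa) pos <- c(pos, tx[[ch]]$pos)
    for (sg in lineages$subgenomes) pos <- c(pos, sg[[ch]]$pos)
    for (p in parents) {
      for (sg in p) {
        pos <- c(pos, sg[[ch]]$h1$pos, sg[[ch]]$h2$pos)
      }
    }
    if (!is.null(transpositions)) {
      tp_ch <- transpositions[transpositions$donor_chrom == ch, ,
                              drop = FALSE]
      for (i in seq_len(nrow(tp_ch))) {
        pos <- c(pos, tp_ch$vm[[i]]$pos, tp_ch$het_pos[i])
      }
    }
    pos <- sort(unique(pos))
    tg <- targets[targets$chrom == ch, , drop = FALSE]
    if (nrow(tg) == 0L || length(pos) == 0L) next
    in_window <- vapply(pos, function(p) {
      any(abs(tg$central - p) < read_length)
    }, logical(1))
    pos <- pos[in_window]
    if (length(pos) == 0L) next
    out <- rbind(out, data.frame(
      chrom = ch, pos = pos,
      ref = substring(lineages$reference[[ch]], pos, pos),
      stringsAsFactors = FALSE))
  }
  out
}

#' Evenly spaced capture targets
#'
#' @param config a [sim_config()].
#' @param chrom_names chromosome names.
#' @return data.frame `chrom`, `start`, `end`, `central` (1-kb regions
#'   centred on the targeted site).
#' @export
make_targets <- function(config, chrom_names) {
  n <- config$targets_per_chromosome
  L <- config$chromosome_length
  centers <- round(seq(L / (n + 1), L * n / (n + 1), length.out = n))
  do.call(rbind, lapply(chrom_names, function(ch) {
    data.frame(chrom = ch, start = pmax(1, centers - 500L),
               end = pmin(L, centers + 500L), central = centers,
               stringsAsFactors = FALSE)
  }))
}

#' Per-site base counts for all individuals (fast capture model)
#'
#' Poisson-thins the per-individual target depth across the individual's
#' sequence copies (so depth scales with copy number, 8 copies being the
#' octoploid baseline) and scatters sequencing errors at `error_rate`.
#' Marginally equivalent to drawing full reads and piling them up.
#'
#' @param individuals from [build_individuals()].
#' @param sites data.frame `chrom`, `pos`, `ref` (see
#'   [candidate_sites()]).
#' @param reference named list of chromosome strings.
#' @param config a [sim_config()].
#' @return long data.frame in the layout of [read_pileup()].
#' @export
simulate_pileup_counts <- function(individuals, sites, reference, config) {
  bases <- c("A", "C", "G", "T")
  n_sites <- nrow(sites)
  res <- vector("list", length(individuals))
  for (k in seq_along(individuals)) {
    ind <- individuals[[k]]
    base_copies <- attr(ind, "base_copies")
    lambda <- config$depth / base_copies
    counts <- matrix(0L, nrow = n_sites, ncol = 4L,
                     dimnames = list(NULL, bases))
    for (cp in ind) {
      sel <- which(sites$chrom == cp$chrom & sites$pos >= cp$start &
                     sites$pos <= cp$end)
      if (length(sel) == 0L) next
      b <- .vm_base_at(cp$vm, sites$pos[sel], reference[[cp$chrom]])
      cnt <- stats::rpois(length(sel), lambda)
      for (bb in bases) {
        s2 <- b == bb
        if (any(s2)) {
          counts[sel[s2], bb] <- counts[sel[s2], bb] + cnt[s2]
        }
      }
    }
    if (config$error_rate > 0) {
      for (bb in bases) {
        err <- stats::rbinom(n_sites, counts[, bb], config$error_rate)
        nz <- which(err > 0L)
        for (i in nz) {
          counts[i, bb] <- counts[i, bb] - err[i]
          to <- sample(setdiff(bases, bb), err[i], replace = TRUE)
          for (tb in to) counts[i, tb] <- counts[i, tb] + 1L
        }
      }
    }
    res[[k]] <- data.frame(
      chrom = sites$chrom, pos = sites$pos, ref = sites$ref,
      sample = names(individuals)[k], A = counts[, "A"], C = counts[, "C"],
      G = counts[, "G"], T = counts[, "T"],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out$depth <- out$A + out$C + out$G + out$T
  rownames(out) <- NULL
  out
}

#' Simulate capture reads (alignment records) around targets
#'
#' Draws reads uniformly among an individual's sequence copies over
#' windows centred on the targets, so that every read covers the target
#' centre; per-base errors are independent at `error_rate`. The returned
#' alignments feed [extract_anchored_markers()].
#'
#' @param individuals from [build_individuals()] (subset as needed).
#' @param targets data.frame with `chrom`, `central`.
#' @param reference named list of chromosome strings.
#' @param config a [sim_config()].
#' @return data.frame `sample`, `chrom`, `start`, `seq`.
#' @export
simulate_capture_reads <- function(individuals, targets, reference, config) {
  rl <- config$read_length
  bases <- c("A", "C", "G", "T")
  out <- vector("list", length(individuals) * nrow(targets))
  slot <- 0L
  for (k in seq_along(individuals)) {
    ind <- individuals[[k]]
    base_copies <- attr(ind, "base_copies")
    for (t in seq_len(nrow(targets))) {
      ch <- targets$chrom[t]; ctr <- targets$central[t]
      cover <- which(vapply(ind, function(cp) {
        cp$chrom == ch & cp$start <= ctr & cp$end >= ctr
      }, logical(1)))
      if (length(cover) == 0L) next
      n_reads <- stats::rpois(1L, config$depth * length(cover) / base_copies)
      if (n_reads == 0L) next
      cp_idx <- sample(cover, n_reads, replace = TRUE)
      starts <- ctr - sample.int(rl, n_reads, replace = TRUE) + 1L
      L <- nchar(reference[[ch]])
      starts <- pmax(starts, 1L)
      ends <- pmin(starts + rl - 1L, L)
      # clip to the copy's mapped interval (partial transposed copies)
      cps <- vapply(ind[cp_idx], function(cp) cp$start, numeric(1))
      cpe <- vapply(ind[cp_idx], function(cp) cp$end, numeric(1))
      starts <- pmax(starts, cps); ends <- pmin(ends, cpe)
      seqs <- substring(reference[[ch]], starts, ends)
      for (ci in unique(cp_idx)) {
        rsel <- which(cp_idx == ci)
        vm <- ind[[ci]]$vm
        vsel <- vm$pos >= min(starts[rsel]) & vm$pos <= max(ends[rsel])
        vp <- vm$pos[vsel]; vb <- vm$base[vsel]
        for (vi in seq_along(vp)) {
          hit <- rsel[starts[rsel] <= vp[vi] & ends[rsel] >= vp[vi]]
          if (length(hit) > 0L) {
            off <- vp[vi] - starts[hit] + 1L
            substr(seqs[hit], off, off) <- vb[vi]
          }
        }
      }
      if (config$error_rate > 0) {
        nerr <- stats::rbinom(n_reads, nchar(seqs), config$error_rate)
        for (ri in which(nerr > 0L)) {
          pos <- sample.int(nchar(seqs[ri]), nerr[ri])
          for (pp in pos) {
            substr(seqs[ri], pp, pp) <- sample(bases, 1L)
          }
        }
      }
      slot <- slot + 1L
      out[[slot]] <- data.frame(
        sample = names(individuals)[k], chrom = ch, start = starts,
        seq = seqs, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out[seq_len(slot)])
  if (is.null(res)) {
    res <- data.frame(sample = character(0), chrom = character(0),
                      start = integer(0), seq = character(0))
  }
  rownames(res) <- NULL
  res
}

#' Run the full synthetic experiment
#'
#' Seeds the RNG once from the configuration and produces every component
#' the analysis pipeline consumes: lineages with planted tracts, phased
#' parents with injected heterozygosity, the disomic F1 cross, planted
#' transpositions, capture targets, candidate variant sites, per-site
#' pileup counts for all samples and (optionally) capture reads.
#'
#' @param config a [sim_config()].
#' @param reads logical; also simulate read alignments (default TRUE).
#' @return list with all simulator components plus `truth` (tracts,
#'   transpositions, parental het sites, gametes).
#' @export
simulate_octoploid_experiment <- function(config, reads = TRUE) {
  set.seed(config$seed)
  lineages <- simulate_lineages(config)
  targets <- make_targets(config, lineages$chrom_names)
  par <- simulate_parents(lineages, config)
  progeny <- simulate_cross(config, lineages$chrom_names)
  tp <- simulate_transpositions(lineages, config, targets)
  individuals <- build_individuals(lineages, par$parents, progeny, tp,
                                   config)
  sites <- candidate_sites(lineages, par$parents, tp, targets,
                           read_length = config$read_length)
  counts <- simulate_pileup_counts(individuals, sites, lineages$reference,
                                   config)
  rd <- if (reads) {
    simulate_capture_reads(individuals[setdiff(names(individuals),
                                               "diploid_ref")],
                           targets, lineages$reference, config)
  } else {
    NULL
  }
  list(config = config, lineages = lineages, targets = targets,
       parents = par$parents, progeny = progeny, individuals = individuals,
       sites = sites, counts = counts, reads = rd,
       truth = list(tracts = lineages$tracts, transpositions = tp,
                    het_sites = par$het_truth))
}

#' Base of a diploid taxon at given sites
#'
#' @param lineages from [simulate_lineages()].
#' @param taxon `"vesca"`, `"iinumae"` or `"outgroup"`.
#' @param chrom,pos site coordinates (vectors of equal length).
#' @return character vector of bases.
#' @export
taxon_base <- function(lineages, taxon, chrom, pos) {
  out <- character(length(pos))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    out[sel] <- .vm_base_at(lineages$taxa[[taxon]][[ch]], pos[sel],
                            lineages$reference[[ch]])
  }
  out
}

#' True subgenome haplotype base at given sites
#'
#' @param lineages from [simulate_lineages()].
#' @param subgenome `"Av"`, `"Bi"`, `"B1"` or `"B2"`.
#' @param chrom,pos site coordinates.
#' @return character vector of bases.
#' @export
subgenome_base <- function(lineages, subgenome, chrom, pos) {
  out <- character(length(pos))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    out[sel] <- .vm_base_at(lineages$subgenomes[[subgenome]][[ch]],
                            pos[sel], lineages$reference[[ch]])
  }
  out
}
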