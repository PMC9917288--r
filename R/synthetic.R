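# Synthetic hexaploid serpin-family generator with planted, machine-readable
# ground truth for every pipeline stage.  All randomness is driven by one
# integer seed; identical seeds give bit-identical output.

sub_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + i * 104729) %% 2147483546L) + 1L
}

aa_alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

# positions are 1-based indices into the protein
mutate_protein <- function(protein, positions, rate) {
  chars <- strsplit(protein, "")[[1L]]
  n_mut <- round(rate * length(positions))
  if (n_mut > 0L) {
    at <- sample(positions, n_mut)
    for (p in at) chars[p] <- sample(setdiff(aa_alphabet, chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

#' Build a scaffold serpin protein with a chosen RCL variant
#'
#' Starts from the packaged reference serpin and applies seeded substitutions
#' outside the N-terminal region and the RCL, then installs the requested
#' reactive-centre-loop variant: `LRS` (the reference LR centre), `LES`/`LMS`
#' (P1 Arg replaced by Glu/Met, the Zy-style centres), `hinge_broken` (P17
#' Glu to Ala: RCL present but non-inhibitory) or `missing` (the whole RCL
#' deleted).  Optionally replaces the N-terminus with a hydrophobic signal
#' peptide.
#'
#' @param rcl_variant One of `"LRS"`, `"LES"`, `"LMS"`, `"hinge_broken"`,
#'   `"missing"`.
#' @param seed Integer seed.
#' @param divergence Fraction of mutable positions substituted (default 0).
#' @param length Optional target length; only lengths within the functional
#'   serpin window (330-600) are accepted, realised by trimming or padding the
#'   C-terminal tail after the RCL.
#' @param signal_peptide Install an N-terminal signal peptide?
#' @param base_protein Protein to start from (default: the reference); its RCL
#'   must sit at the reference coordinates.
#' @param ref The [reference_serpin()] providing coordinates.
#' @return Protein string with attributes `p17_index` (0-based, `NA` for the
#'   `missing` variant), `rcl_variant` and `signal_peptide`.
#' @export
make_scaffold_serpin <- function(rcl_variant = c("LRS", "LES", "LMS",
                                                 "hinge_broken", "missing"),
                                 seed = 1L, divergence = 0, length = NULL,
                                 signal_peptide = FALSE, base_protein = NULL,
                                 ref = reference_serpin()) {
  rcl_variant <- match.arg(rcl_variant)
  prot <- if (is.null(base_protein)) ref$protein else base_protein
  if (nchar(prot) != nchar(ref$protein))
    stop("base_protein must match the reference length")
  set.seed(seed)
  p17 <- ref$rcl_start          # 0-based
  p1 <- ref$rcl_end - 1L
  rcl_span <- seq(p17 + 1L, p1 + 4L)          # 1-based, P17..P3'
  mutable <- setdiff(seq_len(nchar(prot)), c(seq_len(30L), rcl_span))
  prot <- mutate_protein(prot, mutable, divergence)
  if (rcl_variant %in% c("LES", "LMS"))
    substr(prot, p1 + 1L, p1 + 1L) <- if (rcl_variant == "LES") "E" else "M"
  if (rcl_variant == "hinge_broken")
    substr(prot, p17 + 1L, p17 + 1L) <- "A"
  p17_out <- p17
  if (rcl_variant == "missing") {
    prot <- paste0(substr(prot, 1L, p17), substr(prot, p1 + 5L, nchar(prot)))
    p17_out <- NA_integer_
  }
  if (signal_peptide) {
    sp <- "MALLLVALLAVSLAAPSMAFVAGLA"   # 25 aa, >=8-residue hydrophobic run
    prot <- paste0(sp, substr(prot, nchar(sp) + 1L, nchar(prot)))
  }
  if (!is.null(length)) {
    if (length < 330L || length > 600L)
      stop("requested length outside the functional serpin window (330-600)")
    if (length < nchar(prot)) {
      if (length < p1 + 5L) stop("cannot trim into the RCL")
      prot <- substr(prot, 1L, length)
    } else if (length > nchar(prot)) {
      prot <- paste0(prot, paste(sample(aa_alphabet, length - nchar(prot),
                                        replace = TRUE), collapse = ""))
    }
  }
  structure(prot, p17_index = p17_out, rcl_variant = rcl_variant,
            signal_peptide = signal_peptide)
}

codons_for <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), gc)
}

back_translate <- function(protein, seed) {
  set.seed(seed)
  tab <- codons_for()
  chars <- strsplit(protein, "")[[1L]]
  paste(vapply(chars, function(a) {
    cand <- tab[[a]]
    cand[sample.int(length(cand), 1L)]
  }, ""), collapse = "")
}

#' Evolve a CDS to a target divergence under a planted dN/dS
#'
#' Proposes random single-base codon changes (uniform over unprotected codon
#' positions), never accepting changes that create a stop codon, and thins
#' non-synonymous (or, for omega > 1, synonymous) proposals so the accepted
#' substitutions realise a non-synonymous/synonymous rate ratio of `omega`.
#' Substitutions are applied until exactly `round(target_divergence *
#' nchar(cds))` acceptances; the realised synonymous and non-synonymous
#' substitution counts are recorded in the result's attributes.
#'
#' @param cds In-frame nucleotide string without internal stops.
#' @param target_divergence Substitutions per nucleotide site.
#' @param omega Planted dN/dS (> 0; `omega = 0` is accepted and yields purely
#'   synonymous change).
#' @param seed Integer seed.
#' @param protected_codons 1-based codon indices never touched (e.g. the RCL).
#' @return The mutated CDS with attributes `n_subs`, `syn_subs`,
#'   `nonsyn_subs`.
#' @export
evolve_cds <- function(cds, target_divergence, omega, seed,
                       protected_codons = integer(0)) {
  if (nchar(cds) %% 3L != 0L) stop("CDS length must be divisible by 3")
  if (omega < 0) stop("omega must be >= 0")
  n_codons <- nchar(cds) %/% 3L
  candidates <- setdiff(seq_len(n_codons), protected_codons)
  if (!length(candidates)) stop("no mutable codons")
  n_target <- round(target_divergence * nchar(cds))
  set.seed(seed)
  codons <- substring(cds, 3L * seq_len(n_codons) - 2L, 3L * seq_len(n_codons))
  acc <- 0L; syn_n <- 0L; nonsyn_n <- 0L
  p_syn <- if (omega > 1) 1 / omega else 1
  p_non <- if (omega > 1) 1 else omega
  max_iter <- 5000L + 600L * n_target
  iter <- 0L
  while (acc < n_target) {
    iter <- iter + 1L
    if (iter > max_iter)
      stop("target divergence unattainable under the given constraints")
    ci <- candidates[sample.int(length(candidates), 1L)]
    pos <- sample.int(3L, 1L)
    cur <- codons[ci]
    alt_base <- sample(setdiff(c("A", "C", "G", "T"),
                               substr(cur, pos, pos)), 1L)
    alt <- cur
    substr(alt, pos, pos) <- alt_base
    if (is_stop(alt)) next
    syn <- identical(codon_aa(cur), codon_aa(alt))
    if (stats::runif(1L) >= (if (syn) p_syn else p_non)) next
    codons[ci] <- alt
    acc <- acc + 1L
    if (syn) syn_n <- syn_n + 1L else nonsyn_n <- nonsyn_n + 1L
  }
  structure(paste(codons, collapse = ""), n_subs = acc, syn_subs = syn_n,
            nonsyn_subs = nonsyn_n)
}

parse_pattern <- function(pattern) {
  as.integer(strsplit(pattern, ":")[[1L]])
}

#' Specify a synthetic hexaploid serpin family
#'
#' The defaults define the standard conditions exercised throughout the test
#' suite: 12 triads in a mixed A:B:D pattern census, three phylogenetic
#' clades, 10% nucleotide divergence between homeologues under purifying
#' selection (omega 0.2), all three pseudogene lesion mechanisms, the five
#' reactive-centre variants, two signal-peptide groups, and expression
#' archetypes (grain-specific, ubiquitous, root/spike/leaf-specific, silent)
#' with planted stress responses.
#'
#' @param pattern_mix Named integer vector: planted A:B:D pattern to triad
#'   count.
#' @param divergence Nucleotide substitutions/site between homeologues.
#' @param omega Planted dN/dS for homeologue divergence.
#' @param clade_divergence,triad_divergence Amino-acid substitution rates (on
#'   mutable scaffold positions) applied between the reference and each clade
#'   ancestor, and between a clade ancestor and each triad ancestor.
#' @param duplicate_divergence Extra nucleotide divergence of tandem
#'   duplicates from their parent copy.
#' @param rcl_variants,lesions,signal_peptides,archetypes Optional per-triad
#'   overrides (see Details); `NULL` gives the canonical defaults for the
#'   12-triad mix and plain LRS/none/ubiquitous otherwise.
#' @param stress_plan Optional data frame (`gene_index`, `stress_label`,
#'   `log2fc`) planting stress responses on the ubiquitous triads.
#' @param seed Integer seed.
#' @return An object of class `family_spec`.
#' @export
family_spec <- function(pattern_mix = c("1:1:1" = 6L, "1:2:1" = 2L,
                                        "3:1:1" = 1L, "0:2:1" = 1L,
                                        "1:0:1" = 1L, "0:1:1" = 1L),
                        divergence = 0.10, omega = 0.2,
                        clade_divergence = 0.45, triad_divergence = 0.19,
                        duplicate_divergence = 0.02,
                        rcl_variants = NULL, lesions = NULL,
                        signal_peptides = NULL, archetypes = NULL,
                        seed = 42L) {
  patterns <- rep(names(pattern_mix), pattern_mix)
  n <- length(patterns)
  canonical <- identical(unname(pattern_mix[c("1:1:1", "1:2:1", "3:1:1",
                                              "0:2:1", "1:0:1", "0:1:1")]),
                         c(6L, 2L, 1L, 1L, 1L, 1L))
  if (is.null(rcl_variants)) {
    rcl_variants <- rep("LRS", n)
    if (canonical) rcl_variants[c(4L, 5L, 6L, 12L)] <-
      c("LES", "LMS", "hinge_broken", "missing")
  }
  if (is.null(lesions)) {
    # lesion = list(triad, subgenome, type); applied to the first copy on
    # that subgenome
    lesions <- if (canonical) list(
      list(triad = 1L, subgenome = "B", type = "frameshift"),
      list(triad = 2L, subgenome = "A", type = "splice_defect"),
      list(triad = 3L, subgenome = "D", type = "premature_stop"))
    else list()
  }
  if (is.null(signal_peptides)) {
    signal_peptides <- rep(FALSE, n)
    if (canonical) signal_peptides[c(7L, 11L)] <- TRUE
  }
  if (is.null(archetypes)) {
    archetypes <- rep("ubiquitous", n)
    if (canonical) archetypes <- c("grain", "grain", "grain", "ubiquitous",
                                   "ubiquitous", "ubiquitous", "root",
                                   "spike", "silent", "leaf", "root", "stem")
  }
  stopifnot(length(rcl_variants) == n, length(signal_peptides) == n,
            length(archetypes) == n)
  structure(list(patterns = patterns, n_triads = n,
                 clades = rep(1:3, length.out = n),
                 chromosomes = ((seq_len(n) - 1L) %% 7L) + 1L,
                 divergence = divergence, omega = omega,
                 clade_divergence = clade_divergence,
                 triad_divergence = triad_divergence,
                 duplicate_divergence = duplicate_divergence,
                 rcl_variants = rcl_variants, lesions = lesions,
                 signal_peptides = signal_peptides, archetypes = archetypes,
                 stress_plan = stress_plan_default(archetypes, patterns),
                 seed = as.integer(seed)),
            class = "family_spec")
}

# plant stress responses on the genes of ubiquitous triads: stresses heat and
# drought are assayed on leaf, fusarium on spike
stress_plan_default <- function(archetypes, patterns) {
  ubi <- which(archetypes == "ubiquitous")
  if (!length(ubi)) return(data.frame(triad = integer(0), member = integer(0),
                                      stress_label = character(0),
                                      log2fc = numeric(0)))
  fcs <- list(heat = c(3, 1.5, -1.5, 2, -2, 1, 2.5, -1, 3),
              drought = c(1, -1, 2, -1.5, 1.5, 3, -2, 2, 1.5),
              fusarium = c(2, 1, -1, 1.5, -1.5, 2.5, 1, -2, 2))
  rows <- list()
  g <- 0L
  for (t in ubi) {
    n_mem <- sum(parse_pattern(patterns[t]))
    for (m in seq_len(n_mem)) {
      g <- g + 1L
      for (s in names(fcs)) {
        fc <- fcs[[s]][((g - 1L) %% length(fcs[[s]])) + 1L]
        rows[[length(rows) + 1L]] <- data.frame(
          triad = t, member = m, stress_label = s, log2fc = fc)
      }
    }
  }
  do.call(rbind, rows)
}

#' @export
print.family_spec <- function(x, ...) {
  cat(sprintf("<family_spec> %d triads (%s), %d genes, seed %d\n",
              x$n_triads, paste(unique(x$patterns), collapse = ", "),
              sum(vapply(x$patterns, function(p) sum(parse_pattern(p)), 0L)),
              x$seed))
  invisible(x)
}

# split a CDS string into n_exons pieces with every piece >= 50 bp
split_cds <- function(cds, n_exons) {
  len <- nchar(cds)
  repeat {
    cuts <- sort(sample(seq(60L, len - 60L), n_exons - 1L))
    if (n_exons == 2L || min(diff(cuts)) >= 50L) break
  }
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, len)
  substring(cds, starts, ends)
}

frameshift_insert <- function(pieces, ref_len, trunc_frac = 0.8) {
  at <- nchar(pieces[1L]) %/% 2L
  for (ins in c("TTAATTAA", "TAATTAAT", "CTAATTAG", "TTAGTTAA", "GTAATTAA")) {
    trial <- pieces
    trial[1L] <- paste0(substr(pieces[1L], 1L, at), ins,
                        substr(pieces[1L], at + 1L, nchar(pieces[1L])))
    tr <- translate_cds(paste(trial, collapse = ""))
    if (tr$premature_stop && nchar(tr$protein) < trunc_frac * ref_len)
      return(trial)
  }
  stop("could not plant a truncating frameshift")   # nocov
}

#' Generate a toy hexaploid serpin family with planted ground truth
#'
#' Each triad derives from one ancestral serpin (itself derived from a clade
#' ancestor, which derives from the packaged reference): the ancestor is
#' back-translated and evolved independently into its A/B/D homeologue copies
#' at the specified nucleotide divergence and dN/dS; extra same-subgenome
#' copies are planted as tandem duplicates.  Pseudogene lesions (8-bp exon-1
#' frameshift insertion, GT-to-AT donor mutation, sense-to-stop change) are
#' installed per the lesion plan.  Gene loci (2-4 exons, GT..AG introns,
#' random intergenic spacers, both strands) are assembled into per-chromosome
#' sequences with Traes-style gene identifiers, so every downstream reader
#' and the ID parser can be cross-validated.
#'
#' @param spec A [family_spec()].
#' @return List with `genome` (named chromosome sequences), `models` (list of
#'   `gene_model`), `cds` and `proteins` (named vectors, transcript
#'   orientation), and `truth` (list of data frames: `genes`, `pairs` with
#'   planted omega, and the `spec` itself).
#' @export
make_hexaploid_family <- function(spec = family_spec()) {
  ref <- reference_serpin()
  ref_len <- nchar(ref$protein)
  clade_anc <- lapply(1:3, function(cl) {
    make_scaffold_serpin("LRS", seed = sub_seed(spec$seed, cl),
                         divergence = spec$clade_divergence, ref = ref)
  })
  genes <- list()       # per-gene records before placement
  pairs <- list()
  sk <- 100L
  for (t in seq_len(spec$n_triads)) {
    variant <- spec$rcl_variants[t]
    anc <- make_scaffold_serpin(
      variant, seed = sub_seed(spec$seed, sk <- sk + 1L),
      divergence = spec$triad_divergence,
      signal_peptide = spec$signal_peptides[t],
      base_protein = as.character(clade_anc[[spec$clades[t]]]), ref = ref)
    anc_cds <- paste0(back_translate(as.character(anc),
                                     sub_seed(spec$seed, sk <- sk + 1L)),
                      "TAA")
    n_codons <- nchar(anc_cds) %/% 3L
    protected <- c(seq_len(30L), n_codons)
    if (variant != "missing")
      protected <- c(protected, seq(ref$rcl_start + 1L, ref$rcl_end + 3L))
    counts <- parse_pattern(spec$patterns[t])
    names(counts) <- c("A", "B", "D")
    triad_lesions <- Filter(function(l) l$triad == t, spec$lesions)
    member <- 0L
    triad_genes <- list()
    for (sub in c("A", "B", "D")) {
      parent_cds <- NULL
      for (copy in seq_len(counts[[sub]])) {
        member <- member + 1L
        cds <- if (copy == 1L) {
          evolve_cds(anc_cds, spec$divergence / 2, spec$omega,
                     sub_seed(spec$seed, sk <- sk + 1L), protected)
        } else {
          evolve_cds(parent_cds, spec$duplicate_divergence, spec$omega,
                     sub_seed(spec$seed, sk <- sk + 1L), protected)
        }
        if (copy == 1L) parent_cds <- as.character(cds)
        lesion <- "none"
        if (copy == 1L) {
          hit <- Filter(function(l) l$subgenome == sub, triad_lesions)
          if (length(hit)) lesion <- hit[[1L]]$type
        }
        triad_genes[[member]] <- list(
          triad = t, member = member, subgenome = sub, copy = copy,
          cds = as.character(cds), lesion = lesion,
          n_subs = attr(cds, "n_subs"), syn_subs = attr(cds, "syn_subs"),
          nonsyn_subs = attr(cds, "nonsyn_subs"))
      }
    }
    # planted omega applies to every within-triad pair of intact copies
    intact <- Filter(function(g) g$lesion == "none", triad_genes)
    if (length(intact) >= 2L) {
      for (i in seq_len(length(intact) - 1L)) {
        for (j in seq((i + 1L), length(intact))) {
          pairs[[length(pairs) + 1L]] <- data.frame(
            triad = t, member_a = intact[[i]]$member,
            member_b = intact[[j]]$member, omega = spec$omega)
        }
      }
    }
    genes <- c(genes, triad_genes)
  }
  # gene structure, lesions in the DNA, and placement on chromosomes
  chrom_seq <- list()
  chrom_counter <- list()
  models <- list()
  out_cds <- character(0)
  out_prot <- character(0)
  rows <- list()
  pair_ids <- matrix(NA_character_, nrow = length(pairs), ncol = 2L)
  for (g in genes) {
    set.seed(sub_seed(spec$seed, sk <- sk + 1L))
    t <- g$triad
    cds <- g$cds
    if (g$lesion == "premature_stop") {
      j <- (nchar(cds) %/% 3L * 45L) %/% 100L
      substr(cds, 3L * j - 2L, 3L * j) <- "TAA"
    }
    pieces <- split_cds(cds, sample(2:4, 1L))
    if (g$lesion == "frameshift")
      pieces <- frameshift_insert(pieces, ref_len)
    introns <- vapply(seq_len(length(pieces) - 1L), function(i) {
      paste0("GT", random_dna(sample(76:296, 1L)), "AG")
    }, "")
    if (g$lesion == "splice_defect" && length(introns))
      substr(introns[1L], 1L, 1L) <- "A"
    locus <- pieces[1L]
    ex <- matrix(c(0L, nchar(pieces[1L])), ncol = 2L)
    for (i in seq_along(introns)) {
      locus <- paste0(locus, introns[i], pieces[i + 1L])
      s <- nchar(locus) - nchar(pieces[i + 1L])
      ex <- rbind(ex, c(s, nchar(locus)))
    }
    strand <- sample(c("+", "-"), 1L)
    if (strand == "-") {
      L <- nchar(locus)
      locus <- revcomp(locus)
      ex <- cbind(L - ex[, 2L], L - ex[, 1L])
      ex <- ex[order(ex[, 1L]), , drop = FALSE]
    }
    chrom <- paste0(spec$chromosomes[t], g$subgenome)
    if (is.null(chrom_seq[[chrom]])) {
      chrom_seq[[chrom]] <- ""
      chrom_counter[[chrom]] <- 0L
    }
    spacer <- random_dna(sample(2000:5000, 1L))
    offset <- nchar(chrom_seq[[chrom]]) + nchar(spacer)
    chrom_seq[[chrom]] <- paste0(chrom_seq[[chrom]], spacer, locus)
    ex_abs <- ex + offset
    chrom_counter[[chrom]] <- chrom_counter[[chrom]] + 1L
    gene_id <- sprintf("TraesCS%s02G%06d", chrom,
                       100L * (1000L + chrom_counter[[chrom]]))
    mutated_cds <- paste(pieces, collapse = "")
    tr <- translate_cds(mutated_cds)
    models[[gene_id]] <- new_gene_model(
      gene_id, paste0(gene_id, ".1"), chrom, strand,
      exons = ex_abs, cds = ex_abs,
      pseudogene_flag = FALSE)
    out_cds[gene_id] <- mutated_cds
    out_prot[gene_id] <- tr$protein
    for (p in seq_along(pairs)) {
      if (pairs[[p]]$triad == t && pairs[[p]]$member_a == g$member)
        pair_ids[p, 1L] <- gene_id
      if (pairs[[p]]$triad == t && pairs[[p]]$member_b == g$member)
        pair_ids[p, 2L] <- gene_id
    }
    variant <- spec$rcl_variants[t]
    is_pseudo <- g$lesion != "none"
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = gene_id, triad_id = sprintf("T%02d", t),
      clade = spec$clades[t], chromosome = chrom, subgenome = g$subgenome,
      strand = strand, start = ex_abs[1L, 1L],
      rcl_variant = variant,
      expected_pass = !is_pseudo && variant != "missing",
      expected_class = if (variant == "missing") "unknown"
        else if (variant == "hinge_broken") "non_inhibitory" else "inhibitory",
      expected_centre = switch(variant, LRS = "LRS", LES = "LES", LMS = "LMS",
                               hinge_broken = "LRS", missing = NA_character_),
      expected_is_lr = variant %in% c("LRS", "hinge_broken"),
      signal_peptide = spec$signal_peptides[t],
      lesion = g$lesion, is_pseudogene = is_pseudo,
      archetype = spec$archetypes[t],
      pattern_planted = spec$patterns[t],
      n_subs = g$n_subs, syn_subs = g$syn_subs, nonsyn_subs = g$nonsyn_subs,
      stringsAsFactors = FALSE)
  }
  truth_genes <- do.call(rbind, rows)
  # effective pattern: copies that survive pseudogene exclusion and curation
  eff <- vapply(seq_len(nrow(truth_genes)), function(i) {
    tg <- truth_genes[truth_genes$triad_id == truth_genes$triad_id[i] &
                        truth_genes$expected_pass, , drop = FALSE]
    paste(vapply(c("A", "B", "D"),
                 function(s) sum(tg$subgenome == s), 0L), collapse = ":")
  }, "")
  truth_genes$pattern_effective <- eff
  truth_pairs <- if (length(pairs)) {
    data.frame(gene_a = pair_ids[, 1L], gene_b = pair_ids[, 2L],
               omega = vapply(pairs, function(p) p$omega, 0),
               stringsAsFactors = FALSE)
  } else data.frame(gene_a = character(0), gene_b = character(0),
                    omega = numeric(0))
  genome <- vapply(chrom_seq, identity, "")
  list(genome = genome, models = models, cds = out_cds, proteins = out_prot,
       truth = list(genes = truth_genes, pairs = truth_pairs, spec = spec))
}

#' Write a synthetic family to disk
#'
#' Emits `genome.fa`, `genes.gff3`, `cds.fna`, `proteins.faa` and
#' `truth_genes.tsv` / `truth_pairs.tsv` into a directory.
#'
#' @param family Output of [make_hexaploid_family()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_family <- function(family, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(family$genome, file.path(dir, "genome.fa"))
  write_gff3(family$models, file.path(dir, "genes.gff3"))
  write_fasta(family$cds, file.path(dir, "cds.fna"))
  write_fasta(family$proteins, file.path(dir, "proteins.faa"))
  utils::write.table(family$truth$genes, file.path(dir, "truth_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(family$truth$pairs, file.path(dir, "truth_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Generate a synthetic TPM expression matrix with planted truth
#'
#' Baseline expression follows each gene's archetype (ubiquitous: 5-50 TPM in
#' every tissue; tissue-specific: 8-40 TPM in the target tissue and < 0.5
#' elsewhere; silent: < 0.5 everywhere), stress samples are scaled by
#' 2^(planted log2FC), and every value carries multiplicative lognormal noise
#' of the given coefficient of variation.  Pseudogene copies keep their
#' triad's archetype ("expressed but not translated").
#'
#' @param truth_genes The `truth$genes` table of [make_hexaploid_family()].
#' @param stress_plan Data frame `gene_id`, `stress_label`, `log2fc`; default
#'   taken from the family spec via the `spec` argument.
#' @param spec The `family_spec` (used to resolve the default stress plan).
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (default 0.2).
#' @param seed Integer seed.
#' @return List with `expr` (an `expr_matrix`, not yet floored) and `truth`
#'   (data frames `specificity` and `stress`).
#' @export
make_expression_matrix <- function(truth_genes, stress_plan = NULL,
                                   spec = NULL, noise_cv = 0.2, seed = 42L) {
  set.seed(sub_seed(seed, 77L))
  tissues <- c("root", "leaf", "stem", "spike", "grain")
  combos <- data.frame(
    tissue = c("root", "root", "leaf", "leaf", "leaf", "stem", "stem",
               "spike", "grain", "grain"),
    stage = c("seedling", "vegetative", "seedling", "vegetative",
              "reproductive", "vegetative", "reproductive", "reproductive",
              "reproductive", "grain"))
  cultivars <- c("ChineseSpring", "Azhurnaya")
  samples <- do.call(rbind, lapply(cultivars, function(cv) {
    data.frame(sample_id = sprintf("%s_%s_%s", combos$tissue, combos$stage,
                                   cv),
               tissue = combos$tissue, stage = combos$stage, cultivar = cv,
               condition = "control", stress_label = "", pair_id = "",
               stringsAsFactors = FALSE)
  }))
  stress_design <- data.frame(
    stress_label = c("heat", "drought", "fusarium"),
    tissue = c("leaf", "leaf", "spike"),
    stage = c("vegetative", "vegetative", "reproductive"),
    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(stress_design))) {
    sd_ <- stress_design[i, ]
    for (rep_i in 1:2) {
      cid <- sprintf("%s_ctrl_%d", sd_$stress_label, rep_i)
      sid <- sprintf("%s_stress_%d", sd_$stress_label, rep_i)
      samples <- rbind(samples,
        data.frame(sample_id = cid, tissue = sd_$tissue, stage = sd_$stage,
                   cultivar = "ChineseSpring", condition = "control",
                   stress_label = "", pair_id = "", stringsAsFactors = FALSE),
        data.frame(sample_id = sid, tissue = sd_$tissue, stage = sd_$stage,
                   cultivar = "ChineseSpring", condition = "stress",
                   stress_label = sd_$stress_label, pair_id = cid,
                   stringsAsFactors = FALSE))
    }
  }
  if (is.null(stress_plan)) {
    stress_plan <- resolve_stress_plan(truth_genes, spec)
  }
  n_genes <- nrow(truth_genes)
  sigma <- sqrt(log(1 + noise_cv^2))
  noise <- function(n) stats::rlnorm(n, meanlog = -sigma^2 / 2, sdlog = sigma)
  base <- matrix(0, n_genes, length(tissues),
                 dimnames = list(truth_genes$gene_id, tissues))
  spec_rows <- list()
  for (i in seq_len(n_genes)) {
    arch <- truth_genes$archetype[i]
    if (arch == "ubiquitous") {
      base[i, ] <- stats::runif(length(tissues), 5, 50)
      lab <- "ubiquitous"; tset <- paste(sort(tissues), collapse = ",")
    } else if (arch == "silent") {
      base[i, ] <- stats::runif(length(tissues), 0, 0.2)
      lab <- "not_expressed"; tset <- ""
    } else {
      base[i, ] <- stats::runif(length(tissues), 0, 0.2)
      base[i, arch] <- stats::runif(1, 8, 40)
      lab <- "specific"; tset <- arch
    }
    spec_rows[[i]] <- data.frame(gene_id = truth_genes$gene_id[i],
                                 label = lab, tissues = tset,
                                 stringsAsFactors = FALSE)
  }
  tpm <- matrix(0, n_genes, nrow(samples),
                dimnames = list(truth_genes$gene_id, samples$sample_id))
  for (j in seq_len(nrow(samples))) {
    fc <- rep(0, n_genes)
    if (samples$condition[j] == "stress") {
      hit <- stress_plan[stress_plan$stress_label == samples$stress_label[j], ]
      fc[match(hit$gene_id, truth_genes$gene_id)] <- hit$log2fc
    }
    tpm[, j] <- base[, samples$tissue[j]] * 2^fc * noise(n_genes)
  }
  truth_stress <- stress_plan
  truth_stress$expected_direction <- ifelse(truth_stress$log2fc > 0.5, "up",
                                     ifelse(truth_stress$log2fc < -0.5,
                                            "down", "none"))
  list(expr = expression_matrix(tpm, samples),
       truth = list(specificity = do.call(rbind, spec_rows),
                    stress = truth_stress))
}

resolve_stress_plan <- function(truth_genes, spec) {
  if (is.null(spec) || !nrow(spec$stress_plan))
    return(data.frame(gene_id = character(0), stress_label = character(0),
                      log2fc = numeric(0)))
  plan <- spec$stress_plan
  ids <- character(nrow(plan))
  for (i in seq_len(nrow(plan))) {
    tg <- truth_genes[truth_genes$triad_id == sprintf("T%02d", plan$triad[i]), ]
    ids[i] <- tg$gene_id[plan$member[i]]
  }
  data.frame(gene_id = ids, stress_label = plan$stress_label,
             log2fc = plan$log2fc, stringsAsFactors = FALSE)
}
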