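# Seeded synthetic fixture generator: a small reference genome with CpG
# islands carrying literally planted restriction sites, plus SNP, repeat and
# gene annotation tracks, and a truth table of every planted feature. Stands
# in for a real reference genome plus UCSC annotation tracks so the whole
# pipeline is testable offline.

#' Specify a synthetic fixture
#'
#' @param n_chroms Number of chromosomes.
#' @param chrom_length Length of each chromosome (bp).
#' @param n_cpg_islands Total number of CpG islands (distributed across
#'   chromosomes round-robin).
#' @param island_length Island width (bp).
#' @param n_snps Total number of single-bp SNP records.
#' @param n_repeats Total number of repeat-element intervals.
#' @param repeat_length Repeat interval width (bp).
#' @param n_genes Total number of gene intervals (stranded).
#' @param gene_length Gene interval width (bp).
#' @param planted_enzyme_sites Named list, `list(HpaII = 1)` or
#'   `list(HpaII = c(1, 0, 2))`: per-enzyme counts of recognition sites
#'   planted in each island (vectors are recycled across islands).
#' @param scrub_chance_sites If `TRUE` (default), background occurrences of
#'   the planted enzymes' recognition motifs are mutated away, so the truth
#'   table is the complete site list for those enzymes.
#' @param seed Integer RNG seed; the fixture is a pure function of this spec.
#' @return An object of class `msre_fixture_spec`.
#' @export
fixture_spec <- function(n_chroms = 1L, chrom_length = 50000L,
                         n_cpg_islands = 8L, island_length = 600L,
                         n_snps = 40L, n_repeats = 10L, repeat_length = 300L,
                         n_genes = 6L, gene_length = 1200L,
                         planted_enzyme_sites = list(HpaII = 1L),
                         scrub_chance_sites = TRUE, seed = 1L) {
  counts <- c(n_chroms, chrom_length, n_cpg_islands, island_length, n_snps,
              n_repeats, repeat_length, n_genes, gene_length)
  if (any(counts < 0)) stop("fixture counts must be >= 0", call. = FALSE)
  if (n_chroms < 1) stop("need at least one chromosome", call. = FALSE)
  structure(list(n_chroms = as.integer(n_chroms),
                 chrom_length = as.integer(chrom_length),
                 n_cpg_islands = as.integer(n_cpg_islands),
                 island_length = as.integer(island_length),
                 n_snps = as.integer(n_snps),
                 n_repeats = as.integer(n_repeats),
                 repeat_length = as.integer(repeat_length),
                 n_genes = as.integer(n_genes),
                 gene_length = as.integer(gene_length),
                 planted_enzyme_sites = planted_enzyme_sites,
                 scrub_chance_sites = isTRUE(scrub_chance_sites),
                 seed = as.integer(seed)),
            class = "msre_fixture_spec")
}

# sample non-overlapping interval starts by rejection; hard error if a
# feature cannot be placed (never silent truncation)
#' @noRd
place_intervals <- function(chrom_length, widths, occupied, margin = 100L,
                            max_tries = 2000L) {
  starts <- integer(0)
  for (w in widths) {
    placed <- FALSE
    for (k in seq_len(max_tries)) {
      s <- sample.int(chrom_length - w - 2L * margin, 1L) + margin
      if (!any(overlaps(s, s + w, occupied$start, occupied$end))) {
        occupied <- rbind(occupied, data.frame(start = s, end = s + w))
        starts <- c(starts, s)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("could not place a fixture feature of width ", w,
           " without overlap; reduce feature counts or enlarge the chromosome",
           call. = FALSE)
    }
  }
  list(starts = starts, occupied = occupied)
}

# CpG-rich sequence: elevated CG-dinucleotide frequency
#' @noRd
cpg_island_sequence <- function(len) {
  out <- character(0)
  n <- 0L
  while (n < len) {
    if (stats::runif(1) < 0.18 && n + 2L <= len) {
      out <- c(out, "C", "G")
      n <- n + 2L
    } else {
      out <- c(out, sample(c("A", "C", "G", "T"), 1, prob = c(.2, .3, .3, .2)))
      n <- n + 1L
    }
  }
  paste(out, collapse = "")
}

# instantiate a degenerate IUPAC motif into a concrete sequence
#' @noRd
instantiate_motif <- function(pattern) {
  codes <- strsplit(pattern, "")[[1]]
  paste(vapply(codes, function(cc) {
    set <- IUPAC_SETS[[cc]]
    if (length(set) == 1) set else sample(set, 1)
  }, character(1)), collapse = "")
}

#' Generate a synthetic fixture
#'
#' Deterministic for a given spec (including the seed): two runs produce
#' identical genomes, annotation sets, targets and truth tables. Requested
#' enzyme recognition sites are literally planted at recorded positions
#' inside CpG islands; SNPs, repeats and genes are planted at recorded
#' intervals. One design target per island is emitted.
#'
#' @param spec An [fixture_spec()].
#' @return List with `genome` (`msre_genome`), `annotations` (named list of
#'   `msre_annotation`: `snp`, `cpg_island`, `repeat`, `gene`), `targets`
#'   (BED4-style data.frame, one per island) and `truth` (data.frame of every
#'   planted feature: `kind`, `chrom`, `start`, `end`, `name`, `enzyme`,
#'   `strand`, `island`, `seq`).
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "msre_fixture_spec"))
  catalog <- enzyme_catalog()
  enz_names <- names(spec$planted_enzyme_sites)
  unknown <- setdiff(tolower(enz_names), tolower(catalog$name))
  if (length(unknown) > 0) {
    stop("planted_enzyme_sites names not in catalog: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  with_local_seed(spec$seed, {
    chroms <- paste0("chr", seq_len(spec$n_chroms))
    seqs <- stats::setNames(
      vapply(chroms, function(x) random_dna(spec$chrom_length), character(1)),
      chroms)
    truth <- list()
    island_rec <- list()

    # distribute feature totals round-robin across chromosomes
    assign_chrom <- function(n) chroms[((seq_len(n) - 1L) %% spec$n_chroms) + 1L]
    island_chrom <- assign_chrom(spec$n_cpg_islands)
    repeat_chrom <- assign_chrom(spec$n_repeats)
    gene_chrom <- assign_chrom(spec$n_genes)

    occupied <- lapply(stats::setNames(chroms, chroms), function(x)
      data.frame(start = integer(), end = integer()))

    place_on <- function(chrom_vec, width) {
      starts <- integer(length(chrom_vec))
      for (i in seq_along(chrom_vec)) {
        ch <- chrom_vec[i]
        p <- place_intervals(spec$chrom_length, width, occupied[[ch]])
        occupied[[ch]] <<- p$occupied
        starts[i] <- p$starts
      }
      starts
    }

    island_start <- place_on(island_chrom, spec$island_length)
    repeat_start <- place_on(repeat_chrom, spec$repeat_length)
    gene_start <- place_on(gene_chrom, spec$gene_length)

    # islands: rewrite with CpG-rich sequence, then plant enzyme sites
    site_truth <- list()
    for (i in seq_along(island_start)) {
      ch <- island_chrom[i]
      s0 <- island_start[i]
      isl_seq <- cpg_island_sequence(spec$island_length)
      planted <- data.frame(start = integer(), end = integer())
      for (enz in enz_names) {
        counts <- spec$planted_enzyme_sites[[enz]]
        k <- counts[((i - 1L) %% length(counts)) + 1L]
        if (k == 0) next
        row <- catalog[tolower(catalog$name) == tolower(enz), , drop = FALSE]
        motif_len <- nchar(row$recognition)
        for (j in seq_len(k)) {
          ok <- FALSE
          for (try in 1:2000) {
            off <- sample.int(spec$island_length - motif_len, 1L)
            if (!any(overlaps(off, off + motif_len, planted$start, planted$end))) {
              ok <- TRUE
              break
            }
          }
          if (!ok) {
            stop("could not plant ", row$name, " site #", j, " in island ", i,
                 call. = FALSE)
          }
          concrete <- instantiate_motif(row$recognition)
          substr(isl_seq, off + 1L, off + motif_len) <- concrete
          planted <- rbind(planted, data.frame(start = off, end = off + motif_len))
          site_truth[[length(site_truth) + 1L]] <- data.frame(
            kind = "enzyme_site", chrom = ch, start = s0 + off,
            end = s0 + off + motif_len,
            name = sprintf("site_%s_%d_%d", row$name, i, j),
            enzyme = row$name, strand = "+", island = i, seq = concrete,
            stringsAsFactors = FALSE)
        }
      }
      substr(seqs[[ch]], s0 + 1L, s0 + spec$island_length) <- isl_seq
      island_rec[[i]] <- data.frame(
        kind = "cpg_island", chrom = ch, start = s0,
        end = s0 + spec$island_length, name = sprintf("island_%d", i),
        enzyme = NA_character_, strand = NA_character_, island = i,
        seq = NA_character_, stringsAsFactors = FALSE)
    }
    truth <- c(island_rec, site_truth)

    # SNPs: single-bp records anywhere (may overlap other features)
    if (spec$n_snps > 0) {
      snp_chrom <- assign_chrom(spec$n_snps)
      for (i in seq_len(spec$n_snps)) {
        p <- sample.int(spec$chrom_length - 2L, 1L)
        truth[[length(truth) + 1L]] <- data.frame(
          kind = "snp", chrom = snp_chrom[i], start = p, end = p + 1L,
          name = sprintf("rs%06d", i), enzyme = NA_character_,
          strand = NA_character_, island = NA_integer_, seq = NA_character_,
          stringsAsFactors = FALSE)
      }
    }
    for (i in seq_along(repeat_start)) {
      truth[[length(truth) + 1L]] <- data.frame(
        kind = "repeat", chrom = repeat_chrom[i], start = repeat_start[i],
        end = repeat_start[i] + spec$repeat_length,
        name = sprintf("rep_%d", i), enzyme = NA_character_,
        strand = NA_character_, island = NA_integer_, seq = NA_character_,
        stringsAsFactors = FALSE)
    }
    for (i in seq_along(gene_start)) {
      truth[[length(truth) + 1L]] <- data.frame(
        kind = "gene", chrom = gene_chrom[i], start = gene_start[i],
        end = gene_start[i] + spec$gene_length,
        name = sprintf("gene_%d", i), enzyme = NA_character_,
        strand = sample(c("+", "-"), 1), island = NA_integer_,
        seq = NA_character_, stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, truth)

    # scrub chance occurrences of planted motifs so the truth table is the
    # complete site list for the planted enzymes
    if (spec$scrub_chance_sites && length(enz_names) > 0) {
      planted_sites <- truth[truth$kind == "enzyme_site", , drop = FALSE]
      enz_rows <- catalog[match(tolower(enz_names), tolower(catalog$name)), ,
                          drop = FALSE]
      for (ch in chroms) {
        keep <- planted_sites[planted_sites$chrom == ch, , drop = FALSE]
        for (round in 1:100) {
          found <- scan_sites_multi(seqs[[ch]], enz_rows)
          extra <- found[!(paste(found$enzyme, found$position) %in%
                             paste(keep$enzyme, keep$start)), , drop = FALSE]
          if (nrow(extra) == 0) break
          if (round == 100) {
            stop("failed to scrub chance enzyme sites on ", ch, call. = FALSE)
          }
          for (r in seq_len(nrow(extra))) {
            cand <- seq(extra$position[r], extra$position[r] + extra$len[r] - 1L)
            cand <- cand[!vapply(cand, function(p)
              any(p >= keep$start & p < keep$end), logical(1))]
            if (length(cand) == 0) next # shares every base with a planted site
            p <- cand[sample.int(length(cand), 1L)]
            cur <- substr(seqs[[ch]], p + 1L, p + 1L)
            repl <- sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
            substr(seqs[[ch]], p + 1L, p + 1L) <- repl
          }
        }
      }
    }

    genome <- new_genome(seqs)
    ann_of <- function(kind_truth, kind_label) {
      rec <- truth[truth$kind == kind_truth,
                   c("chrom", "start", "end", "name", "strand"), drop = FALSE]
      rec <- rec[order(rec$chrom, rec$start, rec$end, rec$name), , drop = FALSE]
      rownames(rec) <- NULL
      new_annotation(kind_label, rec)
    }
    targets <- truth[truth$kind == "cpg_island",
                     c("chrom", "start", "end"), drop = FALSE]
    targets$target_id <- sprintf("tgt_%03d", seq_len(nrow(targets)))
    rownames(targets) <- NULL

    list(genome = genome,
         annotations = list(
           snp = ann_of("snp", "snp"),
           cpg_island = ann_of("cpg_island", "cpg_island"),
           "repeat" = ann_of("repeat", "repeat"),
           gene = ann_of("gene", "gene")),
         targets = targets,
         truth = truth)
  })
}

#' Write fixture files to a directory
#'
#' Writes `genome.fa`, `snp.bed`, `cpg.bed`, `repeats.bed`, `genes.bed`,
#' `targets.bed` and `truth.tsv`.
#'
#' @param fixture Result of [generate_fixture()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             snp = file.path(dir, "snp.bed"),
             cpg = file.path(dir, "cpg.bed"),
             repeats = file.path(dir, "repeats.bed"),
             genes = file.path(dir, "genes.bed"),
             targets = file.path(dir, "targets.bed"),
             truth = file.path(dir, "truth.tsv"))
  write_fasta(fixture$genome, paths[["genome"]])
  write_bed(fixture$annotations$snp, paths[["snp"]])
  write_bed(fixture$annotations$cpg_island, paths[["cpg"]])
  write_bed(fixture$annotations$`repeat`, paths[["repeats"]])
  write_bed(fixture$annotations$gene, paths[["genes"]])
  write_bed(fixture$targets, paths[["targets"]])
  utils::write.table(fixture$truth, paths[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
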