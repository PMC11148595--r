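# Synthetic fixtures: toy taxonomies, mock virus-bacteria communities with
# error-bearing reads and ground-truth labels.

.dmpLine <- function(...) paste0(paste(..., sep = "\t|\t"), "\t|")

#' Generate a toy taxdump
#'
#' Writes \code{nodes.dmp} and \code{names.dmp} in the pipe-delimited dmp
#' dialect: a global root (taxid 1), a Viruses superkingdom (taxid 10239)
#' with \code{nViralFamilies} independent full phylum-to-species chains (so
#' two viral families meet only at the virus root, like distinct viral
#' realms), and a Bacteria superkingdom (taxid 2) with one shared
#' phylum/class/order/family chain and \code{nBacterialGenera} genus/species
#' pairs.  The viral side carries no kingdom-ranked node, exercising the
#' superkingdom-to-kingdom fallback of [lineage7()].  Output is
#' deterministic: the same arguments always produce byte-identical files.
#'
#' @param nViralFamilies number of viral family chains (>= 1)
#' @param nBacterialGenera number of bacterial genera (>= 1)
#' @param seed recorded in a header-free reproducible layout (generation is
#'   fully deterministic; the seed participates only in name suffixes)
#' @param dir output directory (created if needed)
#' @return invisibly, a list with \code{nodes}, \code{names} paths and the
#'   per-family species taxids (\code{viral_species},
#'   \code{bacterial_species})
#' @export
synthTaxonomy <- function(nViralFamilies, nBacterialGenera, seed = 1L,
                          dir = tempfile("taxdump")) {
  stopifnot(nViralFamilies >= 1L, nBacterialGenera >= 1L)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  nodes <- list(.dmpLine(1, 1, "no rank"),
                .dmpLine(10239, 1, "superkingdom"),
                .dmpLine(2, 1, "superkingdom"))
  nms <- list(.dmpLine(1, "root", "", "scientific name"),
              .dmpLine(10239, "Viruses", "", "scientific name"),
              .dmpLine(2, "Bacteria", "", "scientific name"))
  ranks <- c("phylum", "class", "order", "family", "genus", "species")
  viralSpecies <- integer(nViralFamilies)
  for (i in seq_len(nViralFamilies)) {
    base <- 10000L + i * 100L
    parent <- 10239L
    for (j in seq_along(ranks)) {
      id <- base + j
      nodes[[length(nodes) + 1L]] <- .dmpLine(id, parent, ranks[j])
      nms[[length(nms) + 1L]] <-
        .dmpLine(id, sprintf("Vir%d_%s_s%d", i, ranks[j], seed), "",
                 "scientific name")
      parent <- id
    }
    viralSpecies[i] <- base + length(ranks)
  }
  # shared bacterial backbone: kingdom-less, one phylum/class/order/family
  backbone <- c("phylum", "class", "order", "family")
  parent <- 2L
  for (j in seq_along(backbone)) {
    id <- 500L + j
    nodes[[length(nodes) + 1L]] <- .dmpLine(id, parent, backbone[j])
    nms[[length(nms) + 1L]] <-
      .dmpLine(id, sprintf("Bac_%s_s%d", backbone[j], seed), "",
               "scientific name")
    parent <- id
  }
  bacterialSpecies <- integer(nBacterialGenera)
  for (g in seq_len(nBacterialGenera)) {
    gid <- 600L + g * 10L
    sid <- gid + 1L
    nodes[[length(nodes) + 1L]] <- .dmpLine(gid, 504L, "genus")
    nms[[length(nms) + 1L]] <-
      .dmpLine(gid, sprintf("Bacgen%d_s%d", g, seed), "", "scientific name")
    nodes[[length(nodes) + 1L]] <- .dmpLine(sid, gid, "species")
    nms[[length(nms) + 1L]] <-
      .dmpLine(sid, sprintf("Bacgen%d species_s%d", g, seed), "",
               "scientific name")
    bacterialSpecies[g] <- sid
  }
  nodesPath <- file.path(dir, "nodes.dmp")
  namesPath <- file.path(dir, "names.dmp")
  writeLines(unlist(nodes), nodesPath)
  writeLines(unlist(nms), namesPath)
  invisible(list(nodes = nodesPath, names = namesPath,
                 viral_species = viralSpecies,
                 bacterial_species = bacterialSpecies))
}

.SENSE_CODONS <- {
  b <- c("A", "C", "G", "T")
  all <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all, c("TAA", "TAG", "TGA"))
}

.randomGenome <- function(length) {
  # codon-structured: random sense codons, so the frame-0 translation is an
  # ORF-like protein (no internal stops), as in a gene-dense viral genome
  ncod <- ceiling(length / 3)
  paste(sample(.SENSE_CODONS, ncod, replace = TRUE), collapse = "")
}

#' Specification of a mock virus-bacteria community
#'
#' Bundles the generation parameters: the genomes (label, length, taxid and,
#' for viruses, genome type), reads per genome (total, split evenly across
#' samples), read length, per-base substitution rate and the seed.  Seeded
#' generation is bit-reproducible and every read carries a truth label.
#'
#' @param viralGenomes data.frame: \code{label}, \code{length}, \code{taxid},
#'   \code{genome_type}
#' @param bacterialGenomes data.frame: \code{label}, \code{length},
#'   \code{taxid}
#' @param readsPerGenome total reads simulated per genome
#' @param readLength read length in bases
#' @param substitutionRate per-base substitution probability
#' @param seed RNG seed
#' @param nSamples number of samples the reads are split across
#' @return a classed list (\code{mockCommunitySpec})
#' @export
mockCommunitySpec <- function(viralGenomes, bacterialGenomes,
                              readsPerGenome = 200L, readLength = 150L,
                              substitutionRate = 0.01, seed = 42L,
                              nSamples = 2L) {
  spec <- list(viralGenomes = viralGenomes,
               bacterialGenomes = bacterialGenomes,
               readsPerGenome = as.integer(readsPerGenome),
               readLength = as.integer(readLength),
               substitutionRate = substitutionRate,
               seed = as.integer(seed), nSamples = as.integer(nSamples))
  class(spec) <- "mockCommunitySpec"
  spec
}

.mutateRead <- function(seq, rate) {
  if (rate <= 0) return(seq)
  s <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- which(runif(length(s)) < rate)
  for (i in hit) {
    s[i] <- sample(setdiff(c("A", "C", "G", "T"), s[i]), 1L)
  }
  paste(s, collapse = "")
}

#' Simulate a mock community
#'
#' Generates seeded random genomes (codon-structured, stop-free in frame 0),
#' samples reads uniformly from both strands of each genome with
#' substitutions at the stated per-base rate (substitution-only error model;
#' constant Sanger quality), and emits per-sample FASTQ plus a truth table
#' mapping every read to its source taxid.  Bit-reproducible for a fixed
#' seed.
#'
#' @param spec a [mockCommunitySpec()]
#' @return list: \code{genomes} (named character, all genomes),
#'   \code{viral_labels}, \code{reads} (list per sample of named character
#'   vectors), \code{truth} (data.frame read_id, sample_id, taxid, label,
#'   start, strand)
#' @export
synthCommunity <- function(spec) {
  stopifnot(inherits(spec, "mockCommunitySpec"))
  set.seed(spec$seed)
  gdefs <- rbind(
    data.frame(label = spec$viralGenomes$label,
               length = spec$viralGenomes$length,
               taxid = spec$viralGenomes$taxid, stringsAsFactors = FALSE),
    data.frame(label = spec$bacterialGenomes$label,
               length = spec$bacterialGenomes$length,
               taxid = spec$bacterialGenomes$taxid, stringsAsFactors = FALSE))
  if (any(spec$readLength > gdefs$length))
    stop("readLength exceeds a genome length", call. = FALSE)
  genomes <- setNames(vapply(gdefs$length, .randomGenome, ""), gdefs$label)

  perSample <- spec$readsPerGenome %/% spec$nSamples
  reads <- vector("list", spec$nSamples)
  names(reads) <- sprintf("sample%d", seq_len(spec$nSamples))
  truth <- list()
  for (s in seq_len(spec$nSamples)) {
    sreads <- character(0)
    for (g in seq_len(nrow(gdefs))) {
      glen <- nchar(genomes[[g]])
      starts <- sample.int(glen - spec$readLength + 1L, perSample,
                           replace = TRUE)
      strands <- sample(c("+", "-"), perSample, replace = TRUE)
      ids <- sprintf("%s_s%d_r%03d", gdefs$label[g], s, seq_len(perSample))
      seqs <- substring(genomes[[g]], starts, starts + spec$readLength - 1L)
      rev <- strands == "-"
      if (any(rev))
        seqs[rev] <- as.character(reverseComplement(DNAStringSet(seqs[rev])))
      seqs <- vapply(seqs, .mutateRead, "", rate = spec$substitutionRate,
                     USE.NAMES = FALSE)
      names(seqs) <- ids
      sreads <- c(sreads, seqs)
      truth[[length(truth) + 1L]] <-
        data.frame(read_id = ids, sample_id = names(reads)[s],
                   taxid = gdefs$taxid[g], label = gdefs$label[g],
                   start = starts, strand = strands, stringsAsFactors = FALSE)
    }
    reads[[s]] <- sreads
  }
  list(genomes = genomes, viral_labels = spec$viralGenomes$label,
       reads = reads, truth = do.call(rbind, truth))
}

#' Write a mock community to disk
#'
#' Genomes as FASTA, reads as per-sample FASTQ (constant quality
#' \code{"I"}), truth as TSV.
#'
#' @param community list from [synthCommunity()]
#' @param dir output directory
#' @return invisibly, the written paths
#' @export
writeCommunity <- function(community, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  gpath <- file.path(dir, "genomes.fasta")
  writeXStringSet(DNAStringSet(community$genomes), gpath)
  fpaths <- character(0)
  for (s in names(community$reads)) {
    rs <- community$reads[[s]]
    fp <- file.path(dir, paste0(s, ".fastq"))
    con <- file(fp, "w")
    writeLines(paste0("@", names(rs), "\n", rs, "\n+\n",
                      strrep("I", nchar(rs))), con)
    close(con)
    fpaths <- c(fpaths, fp)
  }
  tpath <- file.path(dir, "truth.tsv")
  write.table(community$truth, tpath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(list(genomes = gpath, fastq = fpaths, truth = tpath))
}

#' Read a FASTQ into a named character vector
#'
#' @param path FASTQ path (4-line records, uncompressed)
#' @return named character vector of read sequences
#' @export
readFastq <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ids <- sub("^@", "", sub("\\s.*$", "", lines[seq(1L, length(lines), 4L)]))
  setNames(lines[seq(2L, length(lines), 4L)], ids)
}

#' Build the four toy reference databases from a mock community
#'
#' Viral amino acid: frame-0 translations of the viral genomes.
#' Multikingdom amino acid: translations of all genomes.  Viral nucleotide:
#' the viral genomes.  Polymicrobial nucleotide: all genomes.  Each database
#' carries a target-to-taxid map keyed by its sequence ids.
#'
#' @param community list from [synthCommunity()]
#' @param truthTaxids named integer vector label -> taxid (defaults derived
#'   from the community truth table)
#' @return list of four databases, each \code{list(seqs, taxids, type)}
#' @export
buildToyDatabases <- function(community, truthTaxids = NULL) {
  if (is.null(truthTaxids)) {
    tt <- unique(community$truth[, c("label", "taxid")])
    truthTaxids <- setNames(tt$taxid, tt$label)
  }
  translate0 <- function(seqs) {
    out <- vapply(seqs, function(s) {
      n <- nchar(s) - nchar(s) %% 3L
      as.character(translate(DNAString(substring(s, 1L, n))))
    }, "", USE.NAMES = FALSE)
    setNames(out, paste0(names(seqs), "_p1"))
  }
  viral <- community$genomes[community$viral_labels]
  allg <- community$genomes
  vaa <- translate0(viral)
  mkaa <- translate0(allg)
  protTaxid <- function(prots, labels)
    setNames(unname(truthTaxids[labels]), names(prots))
  list(
    viral_aa = list(seqs = vaa,
                    taxids = protTaxid(vaa, community$viral_labels),
                    type = "aa"),
    mk_aa = list(seqs = mkaa, taxids = protTaxid(mkaa, names(allg)),
                 type = "aa"),
    viral_nt = list(seqs = viral,
                    taxids = setNames(unname(truthTaxids[names(viral)]),
                                      names(viral)),
                    type = "nt"),
    poly_nt = list(seqs = allg,
                   taxids = setNames(unname(truthTaxids[names(allg)]),
                                     names(allg)),
                   type = "nt"))
}
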