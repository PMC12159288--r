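#' Genome-evolution simulation configuration
#'
#' Parameters of the birth-death genome-evolution simulator. The defaults
#' reproduce the simulated study conditions: a 15-leaf birth-death species
#' tree (birth 0.01, death 0.001 per lineage), a root genome of 100 genes of
#' 50 kb each (5 Mbp), indels at rate 1e-4 with Zipf-distributed lengths, and
#' duplication / lateral gene transfer rates in 0..0.002, five replicates.
#'
#' Branch lengths are in PAM-like units: one unit is one expected
#' substitution per 100 sites. Substitutions follow a Jukes-Cantor nucleotide
#' process, so over a branch of length t each site differs from its ancestor
#' with probability `(3/4)(1 - exp(-(4/3) t/100))`. Indel, duplication and
#' LGT rates are per site (respectively per gene) per branch-length unit, so
#' the 0.0005-0.002 duplication/LGT magnitudes yield a few to tens of events
#' per lineage over a root-to-leaf length of 100.
#'
#' @param n_leaves Number of surviving leaves (>= 2).
#' @param birth_rate,death_rate Per-lineage birth-death rates of the species
#'   tree.
#' @param n_genes Number of root genes.
#' @param gene_len Length of each root gene in bases.
#' @param root_to_leaf_len Root-to-leaf path length in branch-length units
#'   (the study sweeps 5-300).
#' @param indel_rate Indel events per site per branch-length unit.
#' @param zipf_exponent Exponent of the Zipf indel-length distribution.
#' @param max_indel Truncation of indel lengths, in bases.
#' @param dup_rate Gene duplications per gene per branch-length unit.
#' @param lgt_rate Lateral transfers per gene per branch-length unit.
#' @param seed Integer master seed; the tree topology depends only on
#'   `seed`, `n_leaves` and the birth-death rates, so scenarios that vary
#'   rates share one topology.
#' @param n_replicates Number of replicates (replicates share the tree and
#'   differ only in the mutation RNG stream).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_leaves = 15L, birth_rate = 0.01, death_rate = 0.001,
                       n_genes = 100L, gene_len = 50000L,
                       root_to_leaf_len = 100, indel_rate = 1e-4,
                       zipf_exponent = 1.8, max_indel = 50L, dup_rate = 0,
                       lgt_rate = 0, seed = 1L, n_replicates = 5L) {
  cfg <- list(
    n_leaves = as.integer(n_leaves), birth_rate = birth_rate,
    death_rate = death_rate, n_genes = as.integer(n_genes),
    gene_len = as.integer(gene_len), root_to_leaf_len = root_to_leaf_len,
    indel_rate = indel_rate, zipf_exponent = zipf_exponent,
    max_indel = as.integer(max_indel), dup_rate = dup_rate,
    lgt_rate = lgt_rate, seed = as.integer(seed),
    n_replicates = as.integer(n_replicates)
  )
  if (cfg$n_leaves < 2L) abort("n_leaves must be >= 2")
  rates <- c(cfg$birth_rate, cfg$death_rate, cfg$indel_rate, cfg$dup_rate,
             cfg$lgt_rate)
  if (any(rates < 0)) abort("all rates must be >= 0")
  if (cfg$n_genes < 1L || cfg$gene_len < 1L) {
    abort("n_genes and gene_len must be positive")
  }
  if (cfg$root_to_leaf_len <= 0) abort("root_to_leaf_len must be positive")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d leaves (birth %g, death %g), %d genes x %d bp, depth %g\n",
    x$n_leaves, x$birth_rate, x$death_rate, x$n_genes, x$gene_len,
    x$root_to_leaf_len))
  cat(sprintf("  indel %g (Zipf %g, max %d), dup %g, lgt %g, seed %d\n",
              x$indel_rate, x$zipf_exponent, x$max_indel, x$dup_rate,
              x$lgt_rate, x$seed))
  invisible(x)
}

#' Simulate the species tree
#'
#' Samples a birth-death tree conditioned on `n_leaves` surviving species
#' (via [ape::rphylo()]), then rescales it so every root-to-leaf path equals
#' `root_to_leaf_len` exactly (the sampled tree is already ultrametric; the
#' rescaling only changes units). Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return An ultrametric `phylo` tree with leaf labels `G01`, `G02`, ...
#' @export
simulate_tree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  tr <- ape::rphylo(config$n_leaves, birth = config$birth_rate,
                    death = config$death_rate, fossils = FALSE)
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length * (config$root_to_leaf_len / depth)
  tr$tip.label <- sprintf("G%02d", seq_len(config$n_leaves))
  tr
}

#' Generate the root genome
#'
#' A concatenation of `n_genes` i.i.d.-uniform ACGT genes of `gene_len` bases
#' each, annotated with distinct ortholog-family ids. With the default study
#' configuration (100 genes of 50 kb) the root genome is 5 Mbp.
#'
#' @param config A [sim_config()].
#' @param seed Optional seed; defaults to `config$seed`.
#' @return A `genome_record`: a list with `id`, `genes` (character vector of
#'   per-gene sequences), `families` (integer family ids) and `provenance`.
#' @export
generate_root_genome <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  genes <- vapply(seq_len(config$n_genes),
                  function(i) random_genome(config$gene_len), character(1))
  new_genome_record("root", genes, seq_len(config$n_genes),
                    rep("root", config$n_genes))
}

new_genome_record <- function(id, genes, families, provenance) {
  structure(list(id = id, genes = genes, families = as.integer(families),
                 provenance = provenance),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %d genes, %d bp\n", x$id,
              length(x$genes), sum(nchar(x$genes))))
  invisible(x)
}

#' Concatenated sequence of a genome record
#' @param g A `genome_record`.
#' @return A single string (genes are contiguous; intergenic space is
#'   zero-length).
#' @export
genome_seq <- function(g) paste(g$genes, collapse = "")

#' Gene annotation table of a genome record
#' @param g A `genome_record`.
#' @return A tibble with 0-based half-open `start`/`end`, `family`,
#'   `provenance`.
#' @export
genome_annotation <- function(g) {
  len <- nchar(g$genes)
  end <- cumsum(len)
  tibble::tibble(start = end - len, end = end, family = g$families,
                 provenance = g$provenance)
}

BASES_INT <- c(65L, 67L, 71L, 84L) # A C G T

zipf_lengths <- function(n, exponent, max_len) {
  if (n == 0L) return(integer(0))
  sample.int(max_len, n, replace = TRUE,
             prob = (seq_len(max_len))^(-exponent))
}

# Substitutions + indels on one gene (integer-coded), given branch length in
# PAM-like units. Returns the evolved integer vector.
evolve_gene_int <- function(v, branch_len, config) {
  L <- length(v)
  if (L == 0L || branch_len <= 0) return(v)
  # Jukes-Cantor: per-site substitution probability
  p <- 0.75 * (1 - exp(-(4 / 3) * branch_len / 100))
  nsub <- rbinom(1L, L, p)
  if (nsub > 0L) {
    pos <- sample.int(L, nsub)
    cur <- match(v[pos], BASES_INT)
    new <- ((cur - 1L + sample.int(3L, nsub, replace = TRUE)) %% 4L) + 1L
    v[pos] <- BASES_INT[new]
  }
  nind <- rpois(1L, L * config$indel_rate * branch_len)
  for (i in seq_len(nind)) {
    Lc <- length(v)
    len <- zipf_lengths(1L, config$zipf_exponent, config$max_indel)
    pos <- sample.int(Lc, 1L)
    if (runif(1) < 0.5) {
      # deletion, truncated at the gene boundary; keep at least one base
      to <- min(pos + len - 1L, Lc)
      if (to - pos + 1L < Lc) v <- v[-(pos:to)]
    } else {
      ins <- BASES_INT[sample.int(4L, len, replace = TRUE)]
      v <- append(v, ins, after = pos)
    }
  }
  v
}

#' Evolve a genome along one branch
#'
#' Applies, in order: (i) Jukes-Cantor substitutions - each site changes with
#' probability `(3/4)(1 - exp(-(4/3) branch_len/100))` to a uniformly chosen
#' different base; (ii) indels - Poisson(`sites x indel_rate x branch_len`)
#' events with Zipf(`zipf_exponent`) lengths truncated at `max_indel`,
#' insertion/deletion equiprobable, positions uniform (deletions are
#' truncated at gene boundaries; genes are never deleted entirely); (iii)
#' duplications - Poisson(`genes x dup_rate x branch_len`) events, each
#' copying a uniformly chosen gene to a uniformly chosen intergenic position,
#' with the copy recorded. A zero-length branch returns the genome unchanged.
#'
#' @param genome A `genome_record`.
#' @param branch_len Branch length in PAM-like units (>= 0).
#' @param config A [sim_config()].
#' @return A list with `genome` (the evolved `genome_record`) and `events`
#'   (a tibble of duplication events: `type`, `family`, `position`).
#' @export
evolve_branch <- function(genome, branch_len, config) {
  stopifnot(inherits(genome, "genome_record"), branch_len >= 0)
  if (branch_len == 0) {
    return(list(genome = genome,
                events = tibble::tibble(type = character(0),
                                        family = integer(0),
                                        position = integer(0))))
  }
  genes <- lapply(genome$genes, function(g) {
    evolve_gene_int(utf8ToInt(g), branch_len, config)
  })
  families <- genome$families
  prov <- genome$provenance
  events <- list()
  ndup <- rpois(1L, length(genes) * config$dup_rate * branch_len)
  for (i in seq_len(ndup)) {
    src <- sample.int(length(genes), 1L)
    at <- sample.int(length(genes) + 1L, 1L) - 1L # intergenic slot 0..n
    genes <- append(genes, genes[src], after = at)
    families <- append(families, families[src], after = at)
    prov <- append(prov, "dup", after = at)
    events[[length(events) + 1L]] <-
      tibble::tibble(type = "duplication", family = families[at + 1L],
                     position = at + 1L)
  }
  out <- new_genome_record(
    genome$id, vapply(genes, intToUtf8, character(1)), families, prov
  )
  list(genome = out,
       events = if (length(events)) dplyr::bind_rows(events)
                else tibble::tibble(type = character(0), family = integer(0),
                                    position = integer(0)))
}

#' Simulate a full replicate dataset
#'
#' Generates (or reuses) the species tree, draws the root genome, and evolves
#' it down the tree. Without lateral transfer the tree is traversed
#' depth-first branch by branch. With `lgt_rate > 0` the simulation instead
#' advances all contemporaneous lineages on a discrete time grid of step
#' `root_to_leaf_len / 100`; at each step, Poisson(`lineages x genes x
#' lgt_rate x dt`) transfer events pick a uniform donor and a distinct
#' uniform recipient among lineages alive at that time and insert a copy of a
#' uniformly chosen donor gene at a uniform intergenic position of the
#' recipient. Replicates share the tree topology and differ only in the
#' mutation RNG stream.
#'
#' @param config A [sim_config()].
#' @param replicate Replicate index (1-based), used to derive the RNG stream.
#' @param tree Optional pre-computed tree (a `phylo`); defaults to
#'   [simulate_tree()] on `config`, which is deterministic given the seed.
#' @return An object of class `sim_output`: a list with `genomes` (tibble
#'   `id`, `seq`, `genes` list-column of annotation tibbles), `tree`
#'   (`phylo`), `events` (tibble of duplication/LGT events), `orthologs`
#'   (tibble `genome`, `family`, `n_copies`), `config`, `replicate_id`.
#' @export
simulate_dataset <- function(config, replicate = 1L, tree = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(tree)) tree <- simulate_tree(config)
  if (!inherits(tree, "phylo")) abort("tree must be a phylo object")
  set.seed((config$seed * 1009L + as.integer(replicate) * 7919L) %%
             2147483647L)
  # root genome is drawn from the replicate stream (replicates are
  # independent end to end, sharing only the tree topology)
  root_genome <- generate_root_genome(config, seed = NULL)
  ntip <- length(tree$tip.label)
  root_node <- ntip + 1L
  depths <- ape::node.depth.edgelength(tree)
  children_of <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  leaves <- vector("list", ntip)
  all_events <- list()
  log_events <- function(ev, branch_to) {
    if (nrow(ev) > 0) {
      ev$branch <- if (branch_to <= ntip) tree$tip.label[branch_to]
                   else paste0("node", branch_to)
      all_events[[length(all_events) + 1L]] <<- ev
    }
  }
  if (config$lgt_rate == 0) {
    descend <- function(node, genome) {
      kids <- children_of[[as.character(node)]]
      if (is.null(kids)) {
        leaves[[node]] <<- genome
        return(invisible())
      }
      for (e in kids) {
        child <- tree$edge[e, 2]
        res <- evolve_branch(genome, tree$edge.length[e], config)
        if (nrow(res$events) > 0) {
          ev <- res$events
          ev$time <- depths[child]
          log_events(ev, child)
        }
        g2 <- res$genome
        g2$id <- if (child <= ntip) tree$tip.label[child]
                 else paste0("node", child)
        descend(child, g2)
      }
    }
    root_genome$id <- "root"
    descend(root_node, root_genome)
  } else {
    # synchronous time-grid simulation so that LGT can cross lineages
    dt <- config$root_to_leaf_len / 100
    D <- max(depths)
    # a lineage traverses edge e (parent -> child); `at` is its current time
    lineages <- lapply(children_of[[as.character(root_node)]], function(e) {
      list(edge = e, at = depths[root_node], genome = root_genome)
    })
    advance <- function(ln, t2) {
      # evolve lineage to time t2, splitting at speciation nodes on the way;
      # returns a list of lineages
      child <- tree$edge[ln$edge, 2]
      t_child <- depths[child]
      if (t_child > t2 + 1e-12) {
        res <- evolve_branch(ln$genome, t2 - ln$at, config)
        if (nrow(res$events) > 0) {
          ev <- res$events; ev$time <- t2
          log_events(ev, child)
        }
        ln$genome <- res$genome
        ln$at <- t2
        return(list(ln))
      }
      res <- evolve_branch(ln$genome, t_child - ln$at, config)
      if (nrow(res$events) > 0) {
        ev <- res$events; ev$time <- t_child
        log_events(ev, child)
      }
      kids <- children_of[[as.character(child)]]
      if (is.null(kids)) {
        g <- res$genome
        g$id <- tree$tip.label[child]
        leaves[[child]] <<- g
        return(list())
      }
      out <- list()
      for (e in kids) {
        sub <- advance(list(edge = e, at = t_child, genome = res$genome), t2)
        out <- c(out, sub)
      }
      out
    }
    t <- 0
    while (t < D - 1e-9) {
      t2 <- min(t + dt, D)
      lineages <- do.call(c, lapply(lineages, advance, t2 = t2))
      n_alive <- length(lineages)
      if (n_alive >= 2) {
        lam <- n_alive * config$n_genes * config$lgt_rate * (t2 - t)
        n_ev <- rpois(1L, lam)
        for (i in seq_len(n_ev)) {
          donor <- sample.int(n_alive, 1L)
          recip <- sample.int(n_alive - 1L, 1L)
          if (recip >= donor) recip <- recip + 1L
          dg <- lineages[[donor]]$genome
          rg <- lineages[[recip]]$genome
          gi <- sample.int(length(dg$genes), 1L)
          at <- sample.int(length(rg$genes) + 1L, 1L) - 1L
          rg$genes <- append(rg$genes, dg$genes[gi], after = at)
          rg$families <- append(rg$families, dg$families[gi], after = at)
          rg$provenance <- append(rg$provenance, "lgt", after = at)
          lineages[[recip]]$genome <- rg
          all_events[[length(all_events) + 1L]] <- tibble::tibble(
            type = "lgt", family = dg$families[gi], position = at + 1L,
            time = t2,
            branch = paste0("node", tree$edge[lineages[[recip]]$edge, 2]),
            donor = paste0("node", tree$edge[lineages[[donor]]$edge, 2])
          )
        }
      }
      t <- t2
    }
  }
  genome_tbl <- tibble::tibble(
    id = tree$tip.label,
    seq = vapply(seq_len(ntip), function(i) genome_seq(leaves[[i]]),
                 character(1)),
    genes = lapply(seq_len(ntip), function(i) genome_annotation(leaves[[i]]))
  )
  events <- if (length(all_events)) dplyr::bind_rows(all_events)
            else tibble::tibble(type = character(0), family = integer(0),
                                position = integer(0), time = numeric(0),
                                branch = character(0))
  orthologs <- dplyr::bind_rows(lapply(seq_len(ntip), function(i) {
    fam <- leaves[[i]]$families
    tb <- tibble::as_tibble(table(family = fam))
    tibble::tibble(genome = tree$tip.label[i],
                   family = as.integer(tb$family),
                   n_copies = as.integer(tb$n))
  }))
  structure(
    list(genomes = genome_tbl, tree = tree, events = events,
         orthologs = orthologs, config = config,
         replicate_id = as.integer(replicate)),
    class = "sim_output"
  )
}

#' @export
print.sim_output <- function(x, ...) {
  cat(sprintf(
    "<sim_output> replicate %d: %d genomes (mean %.0f bp), %d events\n",
    x$replicate_id, nrow(x$genomes), mean(nchar(x$genomes$seq)),
    nrow(x$events)))
  invisible(x)
}

#' Families in 1:1 orthology between two genomes
#'
#' Uses the simulator's ground-truth ortholog table: a family is 1:1 between
#' two genomes when each carries exactly one copy.
#'
#' @param orthologs The `orthologs` tibble of a `sim_output`.
#' @param g1,g2 Genome ids.
#' @return An integer vector of family ids.
#' @export
one_to_one_families <- function(orthologs, g1, g2) {
  a <- orthologs[orthologs$genome == g1 & orthologs$n_copies == 1L, ]
  b <- orthologs[orthologs$genome == g2 & orthologs$n_copies == 1L, ]
  intersect(a$family, b$family)
}

#' Extract per-family gene sequences from a simulated genome
#'
#' @param sim A `sim_output`.
#' @param genome_id Genome id.
#' @param families Families to keep (default: all).
#' @return A character vector of gene sequences named by family id (repeated
#'   ids possible for duplicated families).
#' @export
gene_sequences <- function(sim, genome_id, families = NULL) {
  i <- match(genome_id, sim$genomes$id)
  if (is.na(i)) abort(paste("unknown genome id:", genome_id))
  ann <- sim$genomes$genes[[i]]
  if (!is.null(families)) ann <- ann[ann$family %in% families, ]
  out <- substring(sim$genomes$seq[i], ann$start + 1L, ann$end)
  names(out) <- ann$family
  out
}
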