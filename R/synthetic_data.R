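#' Specification for a synthetic TF/TAP study system
#'
#' Describes a synthetic genome whose protein families are defined by
#' planted domain architectures, mirroring the structure that rule-based
#' family classification exploits: each family has at least one mandatory
#' domain (the first being a signature unique to that family, so planted
#' membership is unambiguous), forbidden domains are drawn from a disjoint
#' part of the domain vocabulary, genes carry one or more gene models, and
#' decoy sequences carry a forbidden domain alongside their family's
#' mandatory ones. Planted domains are realised as fixed high-information
#' motif strings embedded in random background residues, so a trivial
#' exact-match scanner ([scan_domains()]) can stand in for an HMM-based
#' domain caller.
#'
#' @param n_families number of families.
#' @param n_domains size of the domain vocabulary; defaults to
#'   `2 * n_families + 10`.
#' @param domains_per_family length-2 range of mandatory domains per family.
#' @param mandatory_fraction,forbidden_fraction proportions of the domain
#'   vocabulary allocated to the mandatory and forbidden pools
#'   (must sum to at most 1; the remainder is unused/neutral).
#' @param family_size length-2 range of genes per family.
#' @param models_per_gene length-2 range (>= 1) of gene models per gene.
#' @param decoy_rate probability that a family member additionally carries
#'   a forbidden domain.
#' @param hit_noise probability of a spurious or dropped domain hit in
#'   [generate_domain_hits()].
#' @param n_background number of background sequences with no planted
#'   domains.
#' @param seed integer seed; identical seeds give byte-identical outputs.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_families = 10L,
                           n_domains = NULL,
                           domains_per_family = c(1L, 2L),
                           mandatory_fraction = 0.6,
                           forbidden_fraction = 0.4,
                           family_size = c(2L, 6L),
                           models_per_gene = c(1L, 2L),
                           decoy_rate = 0,
                           hit_noise = 0,
                           n_background = 5L,
                           seed = 1L) {
  if (is.null(n_domains)) n_domains <- 2L * n_families + 10L
  stopifnot(n_families >= 0, n_domains >= 0, n_background >= 0,
            length(domains_per_family) == 2L,
            domains_per_family[1L] >= 1,
            diff(domains_per_family) >= 0,
            length(family_size) == 2L, family_size[1L] >= 0,
            diff(family_size) >= 0,
            length(models_per_gene) == 2L, models_per_gene[1L] >= 1,
            diff(models_per_gene) >= 0)
  stopifnot_proportion(mandatory_fraction, "mandatory_fraction")
  stopifnot_proportion(forbidden_fraction, "forbidden_fraction")
  stopifnot_proportion(decoy_rate, "decoy_rate")
  stopifnot_proportion(hit_noise, "hit_noise")
  if (mandatory_fraction + forbidden_fraction > 1 + 1e-9) {
    stop("mandatory_fraction + forbidden_fraction must be <= 1")
  }
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be an integer")
  structure(list(n_families = as.integer(n_families),
                 n_domains = as.integer(n_domains),
                 domains_per_family = as.integer(domains_per_family),
                 mandatory_fraction = mandatory_fraction,
                 forbidden_fraction = forbidden_fraction,
                 family_size = as.integer(family_size),
                 models_per_gene = as.integer(models_per_gene),
                 decoy_rate = decoy_rate,
                 hit_noise = hit_noise,
                 n_background = as.integer(n_background),
                 seed = seed),
            class = "synthetic_spec")
}

MOTIF_LENGTH <- 15L

random_residues <- function(n) {
  paste(sample(AA_ALPHABET20, n, replace = TRUE), collapse = "")
}

#' Generate a family rule set with planted domain motifs
#'
#' Builds `n_families` families over a domain vocabulary split into a
#' mandatory and a forbidden pool. Every family gets a signature mandatory
#' domain used by no other family (so planted members satisfy exactly one
#' family), optional additional mandatory domains shared from an auxiliary
#' pool, and at least one forbidden domain whenever the forbidden pool is
#' non-empty. A synonym map with alias pairs for the first few families is
#' included. The fixed motif string realising each domain is attached as
#' the `domain_motifs` attribute.
#'
#' @param spec a [synthetic_spec()].
#' @return a [family_rules()] object with attribute `domain_motifs`
#'   (named character vector domain -> motif).
#' @export
generate_rule_set <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  domains <- sprintf("D%03d", seq_len(spec$n_domains))
  motifs <- stats::setNames(
    vapply(domains, function(d) random_residues(MOTIF_LENGTH), ""),
    domains)
  if (spec$n_families == 0L) {
    rules <- family_rules(provenance = "synthetic")
    attr(rules, "domain_motifs") <- motifs
    return(rules)
  }
  n_mand <- floor(spec$n_domains * spec$mandatory_fraction)
  n_forb <- floor(spec$n_domains * spec$forbidden_fraction)
  if (n_mand < spec$n_families) {
    stop("domain vocabulary too small: mandatory pool (", n_mand,
         ") must hold one signature domain per family (", spec$n_families, ")")
  }
  mand_pool <- domains[seq_len(n_mand)]
  forb_pool <- if (n_forb > 0L) domains[n_mand + seq_len(n_forb)] else character()
  signatures <- mand_pool[seq_len(spec$n_families)]
  aux_pool <- setdiff(mand_pool, signatures)
  fam_names <- sprintf("F%03d", seq_len(spec$n_families))
  fams <- stats::setNames(vector("list", spec$n_families), fam_names)
  for (i in seq_len(spec$n_families)) {
    k <- sample_range(spec$domains_per_family[1L],
                      spec$domains_per_family[2L])
    extra <- min(k - 1L, length(aux_pool))
    mandatory <- c(signatures[i],
                   if (extra > 0L) sample(aux_pool, extra) else character())
    forbidden <- if (length(forb_pool)) {
      sample(forb_pool, min(length(forb_pool), sample(1:2, 1L)))
    } else character()
    fams[[i]] <- list(mandatory = mandatory, forbidden = forbidden)
  }
  n_alias <- min(3L, spec$n_families)
  synonyms <- stats::setNames(fam_names[seq_len(n_alias)],
                              paste0(fam_names[seq_len(n_alias)], "-syn"))
  rules <- family_rules(fams, synonyms, provenance = "synthetic")
  attr(rules, "domain_motifs") <- motifs
  rules
}

CODON_TABLE <- NULL  # built lazily; GENETIC_CODE is not available at build

codons_for <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

#' Generate a synthetic proteome with planted family architectures
#'
#' For every family, draws genes (and one or more gene models per gene)
#' whose proteins carry all of the family's mandatory domain motifs planted
#' in random background residues; with probability `decoy_rate` a model
#' additionally carries one of the family's forbidden motifs (a decoy that
#' strict classification must reject). Background sequences carry no
#' planted motifs. Every model also gets a transcript: a random
#' reverse-translation of the protein (standard code, no internal stops)
#' flanked by 0-30 nt UTRs, on the forward or reverse strand, with the
#' coding reading frame recorded in the ground truth.
#'
#' @param rules rule set from [generate_rule_set()] (must carry the
#'   `domain_motifs` attribute).
#' @param spec the [synthetic_spec()] used to size the proteome.
#' @return list of class `synthetic_proteome`: `proteins` and `transcripts`
#'   (named character vectors), `truth` (list with `models` -- one row per
#'   gene model: `sequence_id`, `gene_id`, `family`, `decoy`, `frame`,
#'   `protein_length` -- and `architecture` -- one row per planted domain:
#'   `sequence_id`, `domain`, `start`, `end`), and `spec`.
#' @export
generate_proteome <- function(rules, spec) {
  stopifnot(inherits(rules, "family_rules"), inherits(spec, "synthetic_spec"))
  motifs <- attr(rules, "domain_motifs")
  if (is.null(motifs)) stop("rules lack the 'domain_motifs' attribute")
  if (spec$n_families > length(rules$families)) {
    stop("spec requests more families than the rule set defines")
  }
  if (spec$decoy_rate > 0 &&
      any(!vapply(rules$families, function(f) length(f$forbidden) > 0L, TRUE))) {
    stop("decoy_rate > 0 requires every family to have a forbidden domain")
  }
  set.seed(spec$seed + 1L)
  codon_table <- codons_for()
  codon_table <- lapply(codon_table, function(x) x)  # drop '*' users below
  reverse_translate <- function(protein) {
    aas <- strsplit(protein, "", fixed = TRUE)[[1L]]
    paste(vapply(aas, function(a) {
      cods <- codon_table[[a]]
      cods[sample.int(length(cods), 1L)]
    }, ""), collapse = "")
  }
  models <- list(); arch <- list(); proteins <- character()
  transcripts <- character()
  gene_counter <- 0L
  build_model <- function(model_id, planted_domains) {
    # alternating background / motif segments, coordinates recorded
    n_seg <- length(planted_domains)
    bg_len <- sample(10:40, n_seg + 1L, replace = TRUE)
    pieces <- character(); coords <- list(); pos <- 0L
    for (j in seq_len(n_seg + 1L)) {
      bg <- random_residues(bg_len[j])
      pieces <- c(pieces, bg); pos <- pos + nchar(bg)
      if (j <= n_seg) {
        m <- motifs[[planted_domains[j]]]
        coords[[j]] <- c(pos + 1L, pos + nchar(m))
        pieces <- c(pieces, m); pos <- pos + nchar(m)
      }
    }
    protein <- paste(pieces, collapse = "")
    utr5 <- random_dna(sample(0:30, 1L))
    utr3 <- random_dna(sample(0:30, 1L))
    cds <- reverse_translate(protein)
    fwd <- paste0(utr5, cds, utr3)
    frame_no <- (nchar(utr5) %% 3L) + 1L
    if (stats::runif(1) < 0.5) {
      transcript <- fwd
      frame <- sprintf("+%d", frame_no)
    } else {
      transcript <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(fwd)))
      frame <- sprintf("-%d", frame_no)
    }
    list(protein = protein, transcript = transcript, frame = frame,
         coords = coords)
  }
  for (fi in seq_len(spec$n_families)) {
    fam <- names(rules$families)[fi]
    frule <- rules$families[[fam]]
    n_genes <- sample_range(spec$family_size[1L], spec$family_size[2L])
    for (g in seq_len(n_genes)) {
      gene_counter <- gene_counter + 1L
      gene_id <- sprintf("G%05d", gene_counter)
      n_models <- sample_range(spec$models_per_gene[1L],
                               spec$models_per_gene[2L])
      for (m in seq_len(n_models)) {
        model_id <- sprintf("%s.%d", gene_id, m)
        decoy <- stats::runif(1) < spec$decoy_rate
        planted <- frule$mandatory
        if (decoy) planted <- c(planted, frule$forbidden[1L])
        built <- build_model(model_id, planted)
        proteins[[model_id]] <- built$protein
        transcripts[[model_id]] <- built$transcript
        models[[length(models) + 1L]] <- data.frame(
          sequence_id = model_id, gene_id = gene_id, family = fam,
          decoy = decoy, frame = built$frame,
          protein_length = nchar(built$protein), stringsAsFactors = FALSE)
        arch[[length(arch) + 1L]] <- data.frame(
          sequence_id = model_id, domain = planted,
          start = vapply(built$coords, `[[`, 0L, 1L),
          end = vapply(built$coords, `[[`, 0L, 2L),
          stringsAsFactors = FALSE)
      }
    }
  }
  for (b in seq_len(spec$n_background)) {
    gene_id <- sprintf("B%04d", b)
    model_id <- paste0(gene_id, ".1")
    built <- build_model(model_id, character())
    proteins[[model_id]] <- built$protein
    transcripts[[model_id]] <- built$transcript
    models[[length(models) + 1L]] <- data.frame(
      sequence_id = model_id, gene_id = gene_id, family = NA_character_,
      decoy = FALSE, frame = built$frame,
      protein_length = nchar(built$protein), stringsAsFactors = FALSE)
  }
  truth <- list(
    models = do.call(rbind, models),
    architecture = if (length(arch)) do.call(rbind, arch) else
      data.frame(sequence_id = character(), domain = character(),
                 start = integer(), end = integer())
  )
  rownames(truth$models) <- rownames(truth$architecture) <- NULL
  structure(list(proteins = proteins, transcripts = transcripts,
                 truth = truth, spec = spec),
            class = "synthetic_proteome")
}

random_dna <- function(n) {
  if (n == 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# e-value model for synthetic hits: monotone-decreasing in match length,
# spanning realistic magnitudes, capped at 1e-300
synthetic_evalue <- function(match_length) {
  10^-pmin(match_length / 2, 300)
}

#' Generate a domain-hit table from planted architectures
#'
#' With `hit_noise = 0` the hit table equals the planted architecture
#' exactly. Noise drops each true hit with probability `hit_noise`
#' (`"drop"`/`"both"`) and, independently, adds one spurious hit (random
#' domain at a random position) per model with probability `hit_noise`
#' (`"add"`/`"both"`). E-values are `10^-(match_length / 2)` capped at
#' `1e-300`; bit scores are twice the match length.
#'
#' @param proteome a `synthetic_proteome` (or its `truth` element).
#' @param spec a [synthetic_spec()]; `spec$hit_noise` and `spec$seed`
#'   control corruption and reproducibility.
#' @param noise which corruption to apply: `"both"`, `"drop"` or `"add"`.
#' @return a [domain_hits()] table (protein-level, `frame = NA`).
#' @export
generate_domain_hits <- function(proteome, spec = proteome$spec,
                                 noise = c("both", "drop", "add")) {
  noise <- match.arg(noise)
  truth <- if (inherits(proteome, "synthetic_proteome")) proteome$truth else proteome
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed + 2L)
  a <- truth$architecture
  keep <- rep(TRUE, nrow(a))
  if (spec$hit_noise > 0 && noise %in% c("both", "drop") && nrow(a)) {
    keep <- stats::runif(nrow(a)) >= spec$hit_noise
  }
  a <- a[keep, , drop = FALSE]
  len <- a$end - a$start + 1L
  hits <- domain_hits(a$sequence_id, NA_character_, a$domain,
                      synthetic_evalue(len), 2 * len, a$start, a$end)
  if (spec$hit_noise > 0 && noise %in% c("both", "add")) {
    doms <- sprintf("D%03d", seq_len(spec$n_domains))
    mods <- truth$models
    spurious <- stats::runif(nrow(mods)) < spec$hit_noise
    if (any(spurious)) {
      sm <- mods[spurious, , drop = FALSE]
      start <- vapply(sm$protein_length, function(L) {
        sample.int(max(L - MOTIF_LENGTH, 1L), 1L)
      }, 0L)
      extra <- domain_hits(sm$sequence_id, NA_character_,
                           sample(doms, nrow(sm), replace = TRUE),
                           10^-stats::runif(nrow(sm), 3.5, 20),
                           stats::runif(nrow(sm), 20, 100),
                           start, start + MOTIF_LENGTH - 1L)
      hits <- rbind(hits, extra)
    }
  }
  rownames(hits) <- NULL
  class(hits) <- c("domain_hits", "data.frame")
  hits
}

#' Generate discordant pseudo-pipeline classification outputs
#'
#' Emits the four record tables entering [merge_repertoires()]: one
#' protein-level table and three transcript-level tables from independent
#' pseudo-pipelines. Each transcript source perturbs the true
#' (sequence, frame, family) records at its stated disagreement rate: half
#' of the perturbation probability drops the record, half relabels it to a
#' random other family. Decoy and background models carry no true family
#' and are never emitted.
#'
#' @param proteome a `synthetic_proteome`.
#' @param disagreement numeric length-3 vector of per-source perturbation
#'   proportions, in the order `tfcat`, `itak`, `rule`.
#' @param seed integer seed (defaults to the proteome's seed, offset).
#' @return named list of [pipeline_records()] tables: `protein`, `tfcat`,
#'   `itak`, `rule`.
#' @export
generate_pipeline_outputs <- function(proteome,
                                      disagreement = c(0, 0, 0),
                                      seed = proteome$spec$seed + 3L) {
  stopifnot(inherits(proteome, "synthetic_proteome"),
            length(disagreement) == 3L, all(disagreement >= 0),
            all(disagreement <= 1))
  set.seed(as.integer(seed))
  m <- proteome$truth$models
  m <- m[!is.na(m$family) & !m$decoy, , drop = FALSE]
  fams <- unique(m$family)
  protein <- pipeline_records("protein", "protein", m$sequence_id,
                              NA_character_, m$family)
  perturb <- function(source, rate) {
    u <- stats::runif(nrow(m))
    drop <- u < rate / 2
    relabel <- u >= rate / 2 & u < rate & length(fams) > 1L
    fam <- m$family
    if (any(relabel)) {
      fam[relabel] <- vapply(fam[relabel], function(f) {
        sample(setdiff(fams, f), 1L)
      }, "")
    }
    keep <- !drop
    pipeline_records(source, "transcript", m$sequence_id[keep],
                     m$frame[keep], fam[keep])
  }
  list(protein = protein,
       tfcat = perturb("tfcat", disagreement[1L]),
       itak = perturb("itak", disagreement[2L]),
       rule = perturb("rule", disagreement[3L]))
}

#' Generate a reference transcript set and FPKM matrix
#'
#' Builds a reference "expression atlas": every truth transcript gets
#' exactly one identical reference copy (its planted best hit), plus
#' heavily mutated distractor transcripts whose identity to any query is
#' well below the planted copies. FPKM values are non-negative, drawn
#' log-normally per (transcript, tissue), with a small proportion of
#' transcripts silenced to all-zero rows.
#'
#' @param proteome a `synthetic_proteome`.
#' @param tissues character vector of tissue/condition labels.
#' @param n_distractors number of mutated distractor transcripts.
#' @param seed integer seed.
#' @return list: `reference` (named character vector of transcripts),
#'   `fpkm` (matrix, reference transcripts x tissues), `links`
#'   (data frame `query`, `reference`: the planted best hits).
#' @export
generate_expression <- function(proteome,
                                tissues = c("root", "leaf", "pod_16d"),
                                n_distractors = NULL,
                                seed = proteome$spec$seed + 4L) {
  stopifnot(inherits(proteome, "synthetic_proteome"), length(tissues) >= 1L)
  set.seed(as.integer(seed))
  tx <- proteome$transcripts
  n <- length(tx)
  if (is.null(n_distractors)) n_distractors <- ceiling(0.3 * n)
  ref_ids <- sprintf("VuT%05d", seq_len(n))
  reference <- stats::setNames(unname(tx), ref_ids)
  if (n_distractors > 0L && n > 0L) {
    src <- sample.int(n, n_distractors, replace = TRUE)
    dis <- vapply(src, function(i) mutate_dna(tx[[i]], 0.35), "")
    names(dis) <- sprintf("VuD%04d", seq_len(n_distractors))
    reference <- c(reference, dis)
  }
  fpkm <- matrix(round(stats::rlnorm(length(reference) * length(tissues),
                                     meanlog = 3, sdlog = 1), 2),
                 nrow = length(reference),
                 dimnames = list(names(reference), tissues))
  zero <- stats::runif(nrow(fpkm)) < 0.05
  fpkm[zero, ] <- 0
  links <- data.frame(query = names(tx), reference = ref_ids,
                      stringsAsFactors = FALSE)
  list(reference = reference, fpkm = fpkm, links = links)
}

mutate_dna <- function(seq, rate) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- stats::runif(length(ch)) < rate
  ch[hit] <- vapply(ch[hit], function(b) {
    sample(setdiff(c("A", "C", "G", "T"), b), 1L)
  }, "")
  paste(ch, collapse = "")
}

#' Exact-match domain scanner
#'
#' Stand-in for an HMM-based domain caller on synthetic data: reports every
#' exact occurrence of each domain's motif string in each sequence, with
#' the synthetic E-value model (`10^-(len/2)`). With the planted
#' architectures of [generate_proteome()] this recovers the architecture
#' exactly.
#'
#' @param sequences named character vector of protein sequences (or frame
#'   peptides).
#' @param motifs named character vector domain -> motif string (the
#'   `domain_motifs` attribute of a generated rule set).
#' @param frame optional single frame label recorded on every hit.
#' @return a [domain_hits()] table.
#' @export
scan_domains <- function(sequences, motifs, frame = NA_character_) {
  rows <- list()
  for (sid in names(sequences)) {
    for (dom in names(motifs)) {
      m <- gregexpr(motifs[[dom]], sequences[[sid]], fixed = TRUE)[[1L]]
      if (m[1L] == -1L) next
      len <- attr(m, "match.length")
      rows[[length(rows) + 1L]] <- data.frame(
        sequence_id = sid, frame = frame, domain = dom,
        evalue = synthetic_evalue(len), bitscore = 2 * len,
        start = as.integer(m), end = as.integer(m) + len - 1L,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(domain_hits(character(), character(), character(), numeric(),
                       numeric(), integer(), integer()))
  }
  d <- do.call(rbind, rows)
  domain_hits(d$sequence_id, d$frame, d$domain, d$evalue, d$bitscore,
              d$start, d$end)
}

#' Shared k-mer similarity search (test/demo search contract)
#'
#' A deterministic, alignment-free stand-in for a nucleotide similarity
#' search tool: scores each (query, subject) pair by the fraction of the
#' query's k-mers present in the subject and converts it to a synthetic
#' E-value `10^(-30 * score)`. An identical subject scores 1 (E = 1e-30);
#' heavily mutated distractors score near 0 and fail tight cutoffs.
#'
#' @param queries,db named character vectors of nucleotide sequences.
#' @param k k-mer size (default 11).
#' @param min_score pairs scoring below this are not reported.
#' @return data frame `qseqid`, `sseqid`, `pident`, `evalue`, `bitscore`.
#' @export
kmer_search <- function(queries, db, k = 11L, min_score = 0.1) {
  kmers <- function(s) {
    n <- nchar(s)
    if (n < k) return(character())
    unique(substring(s, 1:(n - k + 1L), k:n))
  }
  db_kmers <- lapply(db, kmers)
  rows <- list()
  for (q in names(queries)) {
    qk <- kmers(queries[[q]])
    if (!length(qk)) next
    for (s in names(db)) {
      score <- mean(qk %in% db_kmers[[s]])
      if (score < min_score) next
      rows[[length(rows) + 1L]] <- data.frame(
        qseqid = q, sseqid = s, pident = 100 * score,
        evalue = 10^(-30 * score), bitscore = 100 * score,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(qseqid = character(), sseqid = character(),
                      pident = numeric(), evalue = numeric(),
                      bitscore = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a tree with planted clades and anchor leaves
#'
#' Builds a rooted tree whose top-level subtrees are the planted groups:
#' each group holds one or more anchor leaves (`anchor_<group>[_i]`) and
#' its query leaves (`q_<group>_<i>`), with short within-group branch
#' lengths and long backbone branches separating groups, so nearest-anchor
#' assignment provably recovers the planted labels.
#'
#' @param groups named integer vector: group label -> number of query
#'   leaves.
#' @param anchors_per_group anchors planted in each group.
#' @param seed integer seed.
#' @return list: `tree` (`phylo`), `anchors` (leaf -> group),
#'   `truth` (query leaf -> group).
#' @export
generate_anchored_tree <- function(groups, anchors_per_group = 1L,
                                   seed = 1L) {
  stopifnot(length(groups) >= 1L, !is.null(names(groups)),
            anchors_per_group >= 1L)
  set.seed(as.integer(seed))
  bl <- function() round(stats::runif(1, 0.05, 0.5), 3)
  subtree <- function(labels) {
    # random nested newick over the labels, branch lengths < 1
    while (length(labels) > 1L) {
      i <- sample.int(length(labels) - 1L, 1L)
      merged <- sprintf("(%s:%.3f,%s:%.3f)", labels[i], bl(),
                        labels[i + 1L], bl())
      labels <- c(labels[seq_len(i - 1L)], merged,
                  labels[-seq_len(i + 1L)])
    }
    labels
  }
  anchors <- character(); truth <- character()
  clades <- vapply(names(groups), function(g) {
    a <- if (anchors_per_group == 1L) paste0("anchor_", g) else
      sprintf("anchor_%s_%d", g, seq_len(anchors_per_group))
    q <- if (groups[[g]] > 0L) sprintf("q_%s_%d", g, seq_len(groups[[g]])) else
      character()
    anchors[a] <<- g
    truth[q] <<- g
    subtree(sample(c(a, q)))
  }, "")
  backbone <- clades[1L]
  for (i in seq_along(clades)[-1L]) {
    backbone <- sprintf("(%s:10,%s:10)", backbone, clades[i])
  }
  tree <- ape::read.tree(text = paste0(backbone, ";"))
  list(tree = tree, anchors = anchors, truth = truth)
}
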