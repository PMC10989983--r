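# Seeded generators for miniature knowledge bases and two-group
# microbiome-metabolome studies with planted structure. These are
# first-class, tested components: they define the study conditions under
# which every downstream stage is exercised offline.

PHYLUM_POOL <- c("Proteobacteria", "Firmicutes", "Bacteroidetes",
                 "Actinobacteria")

#' Specification for a synthetic knowledge base
#'
#' @param seed RNG seed; the generated bundle is a pure function of the
#'   spec.
#' @param n_bacteria,n_archaea,n_fungi,n_animals organism counts per kind.
#' @param n_phyla number of bacterial phyla (drawn from a realistic pool).
#' @param n_metabolites named integer vector of metabolite counts per
#'   origin category (names host, microbiota, cometabolism, food, drug,
#'   environment).
#' @param n_pathways total pathways; the first three are forced to the
#'   host-only / bacteria-only / shared occurrence patterns so every
#'   reference scope is non-trivial.
#' @param pathway_size integer range (min, max) of member metabolites per
#'   pathway.
#' @param n_reactions_per_pathway reactions generated within each pathway.
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, n_bacteria = 12L, n_archaea = 2L,
                         n_fungi = 2L, n_animals = 2L, n_phyla = 3L,
                         n_metabolites = c(host = 10L, microbiota = 16L,
                                           cometabolism = 10L, food = 3L,
                                           drug = 2L, environment = 2L),
                         n_pathways = 8L, pathway_size = c(4L, 8L),
                         n_reactions_per_pathway = 3L) {
  spec <- list(seed = seed, n_bacteria = n_bacteria, n_archaea = n_archaea,
               n_fungi = n_fungi, n_animals = n_animals, n_phyla = n_phyla,
               n_metabolites = n_metabolites, n_pathways = n_pathways,
               pathway_size = pathway_size,
               n_reactions_per_pathway = n_reactions_per_pathway)
  if (any(unlist(spec[c("n_bacteria", "n_animals", "n_pathways")]) < 1))
    stop_input("organism, pathway counts must be positive")
  if (max(pathway_size) > sum(n_metabolites))
    stop_input("pathway size range exceeds the number of metabolites")
  structure(spec, class = "fixture_spec")
}

synth_lineage <- function(i, n_phyla, kind) {
  ph <- if (kind == "bacteria") PHYLUM_POOL[((i - 1) %% n_phyla) + 1]
  else if (kind == "archaea") "Euryarchaeota" else "Ascomycota"
  cl <- paste0(ph, " class ", ((i - 1) %/% n_phyla) %% 2 + 1)
  or <- paste0(cl, " order")
  fa <- paste0(or, " family ", ((i - 1) %/% (2 * n_phyla)) %% 2 + 1)
  ge <- paste0("Genus", kind, ((i - 1) %/% 2) + 1)
  sp <- paste0(ge, " species ", i)
  c(phylum = ph, class = cl, order = or, family = fa, genus = ge,
    species = sp)
}

#' Generate a miniature knowledge base
#'
#' Builds a fully connected synthetic bundle: organisms with complete
#' six-rank lineages, metabolite entries per origin category (produced by
#' running synthetic source records through [merge_sources()], so
#' deduplication is exercised), pathways with guaranteed host-only /
#' bacteria-only / shared occurrence patterns, and reactions with
#' substrates, products, enzymes and organism lists. Deterministic for a
#' fixed spec.
#'
#' @param spec a [fixture_spec()].
#' @return a [metab_kb()].
#' @export
generate_kb <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, generate_kb_impl(spec))
}

generate_kb_impl <- function(spec) {
  # --- organisms ----------------------------------------------------
  mk_orgs <- function(n, kind, prefix) {
    if (n == 0) return(NULL)
    lin <- t(vapply(seq_len(n), synth_lineage, character(6),
                    n_phyla = spec$n_phyla, kind = kind))
    tibble::tibble(org_code = sprintf("%s%02d", prefix, seq_len(n)),
                   name = lin[, "species"], kind = kind,
                   phylum = lin[, "phylum"], class = lin[, "class"],
                   order = lin[, "order"], family = lin[, "family"],
                   genus = lin[, "genus"], species = lin[, "species"])
  }
  animals <- tibble::tibble(
    org_code = c("hsa", sprintf("ani%02d",
                                seq_len(max(0, spec$n_animals - 1)))),
    name = c("host organism",
             sprintf("animal %d", seq_len(max(0, spec$n_animals - 1)))),
    kind = "animal", phylum = "", class = "", order = "", family = "",
    genus = "", species = "")[seq_len(spec$n_animals), ]
  organisms <- dplyr::bind_rows(
    animals,
    mk_orgs(spec$n_bacteria, "bacteria", "bac"),
    mk_orgs(spec$n_archaea, "archaea", "arc"),
    mk_orgs(spec$n_fungi, "fungi", "fun"))

  # --- metabolite entries via synthetic source records --------------
  tag_of <- c(host = "mammal", microbiota = "bacteria",
              cometabolism = "mammal;bacteria", food = "food_plant",
              drug = "drug", environment = "toxin_pollutant")
  cats <- rep(names(spec$n_metabolites), spec$n_metabolites)
  n_met <- length(cats)
  records <- tibble::tibble(
    source_db = "kegg",
    native_id = sprintf("C9%04d", seq_len(n_met)),
    kegg_id = sprintf("C9%04d", seq_len(n_met)),
    hmdb_id = "",
    formula = sprintf("C%dH%dO%d", sample(2:20, n_met, replace = TRUE),
                      sample(4:30, n_met, replace = TRUE),
                      sample(1:10, n_met, replace = TRUE)),
    name = sprintf("%s metabolite %02d", cats, seq_len(n_met)),
    synonyms = "",
    origin_tags = unname(tag_of[cats]))
  # a second source re-reports every third metabolite with an HMDB id
  dup <- records[seq(1, n_met, by = 3), ]
  dup$source_db <- "hmdb"
  dup$native_id <- sprintf("HMDB9%04d", seq_len(nrow(dup)))
  dup$hmdb_id <- dup$native_id
  dup$synonyms <- paste0("syn ", dup$name)
  entries <- suppressWarnings(merge_sources(dplyr::bind_rows(records, dup)))
  entry_cat <- stats::setNames(
    cats[match(purrr::map_chr(split_set(entries$kegg_ids), 1),
               records$kegg_id)], entries$entry_id)

  # --- pathways -----------------------------------------------------
  microbes <- organisms$org_code[organisms$kind %in% MICROBIAL_TAGS]
  bacteria <- organisms$org_code[organisms$kind == "bacteria"]
  host <- "hsa"
  pw_type <- c("host_only", "bacteria_only", "shared",
               sample(c("host_only", "bacteria_only", "shared"),
                      max(0, spec$n_pathways - 3), replace = TRUE))
  pw_type <- pw_type[seq_len(spec$n_pathways)]
  ids_of <- function(categories)
    names(entry_cat)[entry_cat %in% categories]
  pathways <- tibble::tibble(
    pathway_id = sprintf("map9%04d", seq_len(spec$n_pathways)),
    name = sprintf("synthetic pathway %02d (%s)", seq_len(spec$n_pathways),
                   pw_type))
  pathway_members <- purrr::map2(pathways$pathway_id, pw_type, \(pid, ty) {
    # pathways carried only by one side draw at least half their members
    # from that side's own origin category, the rest from co-metabolism
    core <- switch(ty,
                   host_only = ids_of("host"),
                   bacteria_only = ids_of("microbiota"),
                   shared = ids_of("cometabolism"))
    pool <- switch(ty,
                   host_only = ids_of("cometabolism"),
                   bacteria_only = ids_of("cometabolism"),
                   shared = ids_of(c("host", "microbiota")))
    size <- min(length(core) + length(pool),
                sample(spec$pathway_size[1]:spec$pathway_size[2], 1))
    n_core <- min(length(core), max(1, ceiling(size / 2)))
    picked <- c(sample(core, n_core),
                sample(pool, min(length(pool), size - n_core)))
    tibble::tibble(pathway_id = pid, entry_id = sort(picked))
  }) |> dplyr::bind_rows()
  pathway_organisms <- purrr::map2(pathways$pathway_id, pw_type,
                                   \(pid, ty) {
    orgs <- switch(ty,
                   host_only = host,
                   bacteria_only = sample(bacteria,
                                          min(length(bacteria),
                                              max(2, length(bacteria) %/% 2))),
                   shared = c(host, sample(microbes,
                                           min(length(microbes),
                                               max(2, length(microbes) %/% 2)))))
    tibble::tibble(pathway_id = pid, org_code = sort(unique(orgs)))
  }) |> dplyr::bind_rows()

  # --- reactions ----------------------------------------------------
  rx_counter <- 0
  rx <- purrr::map(pathways$pathway_id, function(pid) {
    members <- pathway_members$entry_id[pathway_members$pathway_id == pid]
    orgs <- pathway_organisms$org_code[pathway_organisms$pathway_id == pid]
    purrr::map(seq_len(spec$n_reactions_per_pathway), function(j) {
      rx_counter <<- rx_counter + 1
      rid <- sprintf("R9%04d", rx_counter)
      pair <- sample(members, min(2, length(members)))
      ecs <- sprintf("%d.%d.%d.%d", sample(1:6, 1), sample(1:9, 1),
                     sample(1:9, 1), sample(1:99, 1))
      if (stats::runif(1) < 0.3)
        ecs <- c(ecs, sprintf("%d.%d.%d.%d", sample(1:6, 1),
                              sample(1:9, 1), sample(1:9, 1),
                              sample(1:99, 1)))
      r_orgs <- sample(orgs, max(1, length(orgs) - sample(0:1, 1)))
      list(
        reaction = tibble::tibble(reaction_id = rid),
        pathway = tibble::tibble(reaction_id = rid, pathway_id = pid),
        participants = tibble::tibble(
          reaction_id = rid, entry_id = pair,
          role = c("substrate", "product")[seq_along(pair)]),
        enzymes = tibble::tibble(reaction_id = rid, ec_number = ecs),
        organisms = tibble::tibble(
          reaction_id = rid, org_code = sort(r_orgs),
          ec_number = sample(ecs, length(r_orgs), replace = TRUE)))
    })
  }) |> purrr::flatten()
  pick <- function(field) dplyr::bind_rows(purrr::map(rx, field))

  kb_from_entries(
    entries, organisms = organisms, pathways = pathways,
    pathway_members = pathway_members,
    pathway_organisms = pathway_organisms,
    reactions = pick("reaction"),
    reaction_pathways = pick("pathway"),
    reaction_participants = pick("participants"),
    reaction_enzymes = pick("enzymes"),
    reaction_organisms = pick("organisms"),
    manifest = list(generator = "fixture_spec", seed = spec$seed))
}

#' Origin category of every knowledge-base entry
#'
#' Classifies each entry that carries origin evidence by the same rule as
#' [origin_category()]; handy for auditing generated fixtures.
#'
#' @param kb a [metab_kb()].
#' @return tibble `entry_id`, `category`.
#' @export
kb_entry_categories <- function(kb) {
  ev <- split(kb$entry_origins$origin_tag, kb$entry_origins$entry_id)
  cat <- origin_category(unname(ev))
  tibble::tibble(entry_id = names(ev), category = as.character(cat))
}

#' The canned phenylalanine-metabolism knowledge base
#'
#' A small hand-built (synthetic, non-random) bundle encoding the
#' phenylalanine-metabolism story used throughout the documentation: the
#' pathway contains five reactions (R00693, R01370, R01371, R01424,
#' R06786) touching four differential metabolites (benzoate,
#' phenyllactate, N-acetyl-phenylalanine, 3-hydroxyphenylpropanoate);
#' reaction R00693 acetylates phenylalanine to N-acetyl-phenylalanine via
#' EC 2.3.1.53 and is carried by bacteria spanning the Proteobacteria
#' (Klebsiella, Yersinia, Escherichia) and Firmicutes (Clostridium,
#' Bacillus) phyla. A sixth reaction touching no differential metabolite
#' is included so that filtering is observable.
#'
#' @return a [metab_kb()].
#' @export
phenylalanine_kb <- function() {
  mets <- tibble::tribble(
    ~entry_id, ~kegg, ~name, ~formula, ~tags,
    "MB00001", "C00079", "L-Phenylalanine", "C9H11NO2", "mammal;bacteria",
    "MB00002", "C03519", "N-Acetyl-L-phenylalanine", "C11H13NO3",
    "mammal;bacteria",
    "MB00003", "C00180", "Benzoate", "C7H6O2", "bacteria",
    "MB00004", "C05607", "Phenyllactate", "C9H10O3", "bacteria",
    "MB00005", "C11457", "3-Hydroxyphenylpropanoate", "C9H10O3", "bacteria",
    "MB00006", "C00024", "Acetyl-CoA", "C23H38N7O17P3S", "mammal;bacteria",
    "MB00007", "C00084", "Acetaldehyde", "C2H4O", "mammal;bacteria")
  entries <- tibble::tibble(
    entry_id = mets$entry_id, name = mets$name, formula = mets$formula,
    formulas = mets$formula, kegg_ids = mets$kegg, hmdb_ids = "",
    names = mets$name, origin_tags = mets$tags, source_dbs = "kegg")
  lineages <- tibble::tribble(
    ~org_code, ~genus, ~species, ~phylum, ~class, ~order, ~family,
    "kpn", "Klebsiella", "Klebsiella pneumoniae", "Proteobacteria",
    "Gammaproteobacteria", "Enterobacterales", "Enterobacteriaceae",
    "yen", "Yersinia", "Yersinia enterocolitica", "Proteobacteria",
    "Gammaproteobacteria", "Enterobacterales", "Yersiniaceae",
    "eco", "Escherichia", "Escherichia coli", "Proteobacteria",
    "Gammaproteobacteria", "Enterobacterales", "Enterobacteriaceae",
    "cdf", "Clostridium", "Clostridium difficile", "Firmicutes",
    "Clostridia", "Eubacteriales", "Clostridiaceae",
    "bsu", "Bacillus", "Bacillus subtilis", "Firmicutes", "Bacilli",
    "Bacillales", "Bacillaceae")
  organisms <- dplyr::bind_rows(
    tibble::tibble(org_code = "hsa", name = "host organism",
                   kind = "animal", phylum = "", class = "", order = "",
                   family = "", genus = "", species = ""),
    tibble::tibble(org_code = lineages$org_code, name = lineages$species,
                   kind = "bacteria", phylum = lineages$phylum,
                   class = lineages$class, order = lineages$order,
                   family = lineages$family, genus = lineages$genus,
                   species = lineages$species))
  pathways <- tibble::tibble(pathway_id = "map00360",
                             name = "Phenylalanine metabolism")
  pathway_members <- tibble::tibble(pathway_id = "map00360",
                                    entry_id = mets$entry_id)
  pathway_organisms <- tibble::tibble(
    pathway_id = "map00360",
    org_code = c("hsa", lineages$org_code))
  rx <- tibble::tribble(
    ~reaction_id, ~substrate, ~product, ~ec, ~orgs,
    "R00693", "MB00001", "MB00002", "2.3.1.53",
    c("kpn", "yen", "eco", "cdf", "bsu"),
    "R01370", "MB00001", "MB00004", "1.1.1.110", c("kpn", "cdf"),
    "R01371", "MB00004", "MB00005", "1.14.13.0", c("yen", "bsu"),
    "R01424", "MB00003", "MB00001", "4.1.2.0", c("eco", "cdf"),
    "R06786", "MB00005", "MB00003", "1.2.1.0", c("kpn", "bsu", "cdf"),
    "R09999", "MB00006", "MB00007", "1.1.1.1", c("eco"))
  metab_kb(
    entries = entries[, c("entry_id", "name", "formula", "formulas")],
    entry_xrefs = tibble::tibble(entry_id = mets$entry_id, db = "kegg",
                                 xref_id = mets$kegg),
    entry_names = dplyr::bind_rows(
      tibble::tibble(entry_id = mets$entry_id, name = mets$name),
      tibble::tribble(
        ~entry_id, ~name,
        "MB00001", "Phenylalanine",
        "MB00002", "N-Acetylphenylalanine",
        "MB00003", "Benzoic acid",
        "MB00004", "3-Phenyllactate",
        "MB00005", "3-Hydroxyphenylpropionic acid")),
    entry_origins = tibble::tibble(
      entry_id = rep(mets$entry_id, lengths(split_set(mets$tags))),
      origin_tag = unlist(split_set(mets$tags))),
    entry_sources = tibble::tibble(entry_id = mets$entry_id,
                                   source_db = "kegg"),
    organisms = organisms, pathways = pathways,
    pathway_members = pathway_members,
    pathway_organisms = pathway_organisms,
    reactions = tibble::tibble(reaction_id = rx$reaction_id),
    reaction_pathways = tibble::tibble(reaction_id = rx$reaction_id,
                                       pathway_id = "map00360"),
    reaction_participants = dplyr::bind_rows(
      tibble::tibble(reaction_id = rx$reaction_id,
                     entry_id = rx$substrate, role = "substrate"),
      tibble::tibble(reaction_id = rx$reaction_id, entry_id = rx$product,
                     role = "product")),
    reaction_enzymes = tibble::tibble(reaction_id = rx$reaction_id,
                                      ec_number = rx$ec),
    reaction_organisms = tibble::tibble(
      reaction_id = rep(rx$reaction_id, lengths(rx$orgs)),
      org_code = unlist(rx$orgs),
      ec_number = rep(rx$ec, lengths(rx$orgs))),
    manifest = list(generator = "phenylalanine_kb"))
}

#' The four differential metabolites of the canned fixture
#'
#' @return character vector of entry ids (benzoate, phenyllactate,
#'   N-acetyl-phenylalanine, 3-hydroxyphenylpropanoate).
#' @export
phenylalanine_diff_ids <- function() {
  c("MB00002", "MB00003", "MB00004", "MB00005")
}

# Attenuation of the planted latent correlation caused by multinomial
# counting noise and the rank transform; measured once by Monte-Carlo at
# the generator's default depth/concentration and frozen.
RHO_CALIBRATION <- 1.04

#' Specification for a synthetic two-group study
#'
#' @param seed RNG seed.
#' @param n_per_group samples per group (groups `control` and `case`).
#' @param planted_diff tibble `entry_id`, `log2fc`: metabolites whose case
#'   group is shifted by the given log2 fold change.
#' @param planted_pairs tibble `org_code`, `entry_id`, `rho`: species
#'   whose abundance is coupled to a metabolite through a shared latent
#'   factor calibrated so the realized Spearman correlation approaches
#'   `rho` (|rho| < 1).
#' @param missing_rate fraction of metabolite cells masked completely at
#'   random (in \\[0, 0.5\\]); the default 0 generates complete tables and
#'   missingness is opt-in.
#' @param sdlog metabolite log-normal noise sd (natural log scale).
#' @param depth sequencing depth per sample for the taxa counts.
#' @param concentration Dirichlet-multinomial concentration (smaller =
#'   noisier compositions).
#' @return a `study_spec` list.
#' @export
study_spec <- function(seed = 1L, n_per_group = 15L, planted_diff = NULL,
                       planted_pairs = NULL, missing_rate = 0,
                       sdlog = 0.5, depth = 50000L, concentration = 5) {
  if (missing_rate < 0 || missing_rate > 0.5)
    stop_input("missing_rate must be in [0, 0.5]")
  if (!is.null(planted_pairs) && any(abs(planted_pairs$rho) >= 1))
    stop_input("planted |rho| must be < 1")
  structure(list(seed = seed, n_per_group = n_per_group,
                 planted_diff = planted_diff,
                 planted_pairs = planted_pairs,
                 missing_rate = missing_rate, sdlog = sdlog,
                 depth = depth, concentration = concentration),
            class = "study_spec")
}

#' Generate a synthetic two-group study from a knowledge base
#'
#' Metabolite intensities are log-normal around per-metabolite baselines;
#' planted differential metabolites get a multiplicative case-group shift
#' of `2^log2fc`. Taxa counts are Dirichlet-multinomial at species level
#' (one feature per microbial organism, identified by its full prefixed
#' lineage string). Each planted (species, metabolite) pair shares a
#' per-sample latent Gaussian factor whose loadings are calibrated so the
#' realized Spearman correlation approaches the requested `rho`; targets
#' that would require a latent correlation above the calibration cap
#' trigger a warning reporting the achievable value. Missing values are
#' injected completely at random into the metabolite table at
#' `missing_rate`. Deterministic for a fixed spec.
#'
#' @param kb a [metab_kb()] whose entries/organisms the spec references.
#' @param spec a [study_spec()].
#' @return list with `metabolites` (tibble name/kegg_id/hmdb_id + sample
#'   columns), `taxa` (tibble taxon lineage + sample columns),
#'   `sample_info` (tibble sample_id/group), and `entry_map` (tibble
#'   name/entry_id linking features back to kb entries).
#' @export
generate_study <- function(kb, spec = study_spec()) {
  stopifnot(inherits(kb, "metab_kb"), inherits(spec, "study_spec"))
  if (!is.null(spec$planted_diff) &&
      !all(spec$planted_diff$entry_id %in% kb$entries$entry_id))
    stop_input("planted_diff references entries absent from the kb")
  if (!is.null(spec$planted_pairs) &&
      (!all(spec$planted_pairs$entry_id %in% kb$entries$entry_id) ||
       !all(spec$planted_pairs$org_code %in% kb$organisms$org_code)))
    stop_input("planted_pairs references ids absent from the kb")
  with_seed(spec$seed, generate_study_impl(kb, spec))
}

generate_study_impl <- function(kb, spec) {
  n <- spec$n_per_group
  samples <- sprintf("S%03d", seq_len(2 * n))
  group <- rep(c("control", "case"), each = n)
  entries <- kb$entries
  n_met <- nrow(entries)

  microbes <- kb$organisms[kb$organisms$kind %in% MICROBIAL_TAGS, ]
  if (nrow(microbes) == 0) stop_input("kb contains no microbial organisms")
  lineage <- lineage_string(microbes[, TAXONOMY_RANKS], "species")

  # latent factors for planted pairs
  pairs <- spec$planted_pairs
  z <- NULL
  if (!is.null(pairs) && nrow(pairs) > 0) {
    z <- matrix(stats::rnorm(nrow(pairs) * 2 * n), nrow = nrow(pairs))
    r_latent <- pmin(0.98, abs(pairs$rho) * RHO_CALIBRATION)
    capped <- abs(pairs$rho) * RHO_CALIBRATION > 0.98
    if (any(capped))
      warning("planted rho partially unattainable; achieved latent ",
              "correlation capped at ",
              sprintf("%.2f", 0.98 / RHO_CALIBRATION), call. = FALSE)
    pairs$c_load <- sqrt(r_latent / (1 - r_latent))
    pairs$sign <- sign(pairs$rho)
  }

  # --- metabolites --------------------------------------------------
  mu <- stats::rnorm(n_met, mean = log(1000), sd = 1)
  logx <- matrix(mu, n_met, 2 * n) +
    matrix(stats::rnorm(n_met * 2 * n, sd = spec$sdlog), n_met)
  if (!is.null(spec$planted_diff) && nrow(spec$planted_diff) > 0) {
    ix <- match(spec$planted_diff$entry_id, entries$entry_id)
    logx[ix, group == "case"] <- logx[ix, group == "case"] +
      log(2) * spec$planted_diff$log2fc
  }
  if (!is.null(z)) {
    ix <- match(pairs$entry_id, entries$entry_id)
    logx[ix, ] <- logx[ix, , drop = FALSE] +
      (pairs$c_load * spec$sdlog) * z
  }
  met <- exp(logx)
  if (spec$missing_rate > 0) {
    mask <- matrix(stats::runif(length(met)) < spec$missing_rate,
                   nrow = n_met)
    met[mask] <- NA_real_
  }
  colnames(met) <- samples
  xr <- kb$entry_xrefs
  kegg1 <- vapply(entries$entry_id, function(e) {
    v <- sort(xr$xref_id[xr$entry_id == e & xr$db == "kegg"])
    c(v, "")[1]
  }, character(1))
  hmdb1 <- vapply(entries$entry_id, function(e) {
    v <- sort(xr$xref_id[xr$entry_id == e & xr$db == "hmdb"])
    c(v, "")[1]
  }, character(1))
  met_names <- ifelse(entries$name == "", entries$entry_id, entries$name)
  metab_tbl <- dplyr::bind_cols(
    tibble::tibble(name = met_names, kegg_id = kegg1, hmdb_id = hmdb1),
    tibble::as_tibble(met))

  # --- taxa ---------------------------------------------------------
  n_tax <- nrow(microbes)
  base_lw <- stats::rnorm(n_tax, mean = 0, sd = 1)
  lw <- matrix(base_lw, n_tax, 2 * n)
  # effective log-noise sd of the gamma mixing at this concentration
  s_tax <- sqrt(trigamma(spec$concentration))
  if (!is.null(z)) {
    ix <- match(pairs$org_code, microbes$org_code)
    lw[ix, ] <- lw[ix, , drop = FALSE] +
      (pairs$c_load * s_tax * pairs$sign) * z
  }
  counts <- matrix(0L, n_tax, 2 * n,
                   dimnames = list(lineage, samples))
  for (s in seq_len(2 * n)) {
    g <- stats::rgamma(n_tax, shape = spec$concentration,
                       rate = spec$concentration / exp(lw[, s]))
    g[g <= 0] <- 1e-12
    counts[, s] <- stats::rmultinom(1, spec$depth, g / sum(g))[, 1]
  }
  taxa_tbl <- dplyr::bind_cols(tibble::tibble(taxon = lineage),
                               tibble::as_tibble(counts))

  list(metabolites = metab_tbl,
       taxa = taxa_tbl,
       sample_info = tibble::tibble(sample_id = samples, group = group),
       entry_map = tibble::tibble(name = met_names,
                                  entry_id = entries$entry_id))
}

#' Write a synthetic study as DMOA input files
#'
#' Emits the three input tables (`metabolites.tsv`, `microbiome.tsv`,
#' `sample_info.tsv`) in the shapes [run_dmoa()] reads.
#'
#' @param study a [generate_study()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(study$metabolites, file.path(dir, "metabolites.tsv"),
                   na = "", progress = FALSE)
  readr::write_tsv(study$taxa, file.path(dir, "microbiome.tsv"),
                   na = "", progress = FALSE)
  readr::write_tsv(study$sample_info, file.path(dir, "sample_info.tsv"),
                   na = "", progress = FALSE)
  invisible(dir)
}
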