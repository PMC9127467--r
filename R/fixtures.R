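# Synthetic data generator. Produces a self-contained input bundle with the
# statistical structure the method assumes: planted entity clusters that
# drive gene-set overlap, network edges, fingerprints and symptom profiles,
# and an association matrix generated from a planted nonnegative low-rank
# product aligned with the clusters.

#' Specification of a synthetic fixture
#'
#' @param n_drugs,n_diseases,n_genes Entity counts (defaults 60, 40, 200).
#' @param n_substructures Fingerprint length (default 881).
#' @param n_symptoms Symptom vocabulary size (default 322).
#' @param n_drug_clusters,n_disease_clusters Planted cluster counts
#'   (defaults 3 and 2).
#' @param latent_rank Rank of the planted association score matrix
#'   (default 4).
#' @param density Fraction of drug-disease pairs associated (default 0.15);
#'   the generated matrix has exactly `round(density * n_drugs * n_diseases)`
#'   ones.
#' @param noise Fraction of the ones relocated to random unknown positions
#'   (count-preserving label noise; default 0.02).
#' @param seed Generation seed; the bundle is a deterministic function of the
#'   spec.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_drugs = 60, n_diseases = 40, n_genes = 200,
                         n_substructures = 881, n_symptoms = 322,
                         n_drug_clusters = 3, n_disease_clusters = 2,
                         latent_rank = 4, density = 0.15, noise = 0.02,
                         seed = 1) {
  stopifnot(density > 0, density < 1, noise >= 0, noise < 1,
            n_drug_clusters <= n_drugs, n_disease_clusters <= n_diseases)
  n_ones <- round(density * n_drugs * n_diseases)
  if (n_ones < 1 || n_ones >= n_drugs * n_diseases) {
    abort("requested density is infeasible for this shape")
  }
  structure(
    list(n_drugs = n_drugs, n_diseases = n_diseases, n_genes = n_genes,
         n_substructures = n_substructures, n_symptoms = n_symptoms,
         n_drug_clusters = n_drug_clusters,
         n_disease_clusters = n_disease_clusters,
         latent_rank = latent_rank, density = density, noise = noise,
         seed = seed),
    class = "fixture_spec"
  )
}

# cluster-prototype binary profiles: member keeps a prototype bit with
# probability `keep` and picks up background bits with probability `bg`
prototype_profiles <- function(labels, n_feat, n_proto, keep = 0.9, bg = 0.02) {
  c_n <- max(labels)
  protos <- lapply(seq_len(c_n), function(i) sample.int(n_feat, n_proto))
  m <- matrix(0L, length(labels), n_feat)
  for (i in seq_along(labels)) {
    p <- protos[[labels[i]]]
    on <- p[runif(length(p)) < keep]
    extra <- which(runif(n_feat) < bg)
    m[i, union(on, extra)] <- 1L
  }
  m
}

#' Generate a synthetic input bundle
#'
#' Draws drugs and diseases from planted clusters. Gene sets are sampled
#' mostly from disjoint per-cluster gene pools, so gene-overlap similarity
#' recovers the clusters; known interaction edges and semantic similarities
#' are denser within clusters; fingerprints and symptom profiles are noisy
#' copies of cluster prototypes. The association matrix comes from a planted
#' nonnegative rank-`latent_rank` product whose factors load on the clusters:
#' the top-scoring pairs (exactly `round(density * n * m)` of them) become
#' ones, then a `noise` fraction of the ones are relocated to random unknown
#' positions, preserving the count. Same spec, same bundle, byte for byte.
#'
#' @param spec A [fixture_spec()].
#' @return A list of class `drgcc_fixture` with the association matrix `Y`,
#'   gene incidence maps, interaction edges, semantic similarity,
#'   fingerprints, symptom table, planted cluster labels and planted scores.
#' @export
generate_fixture <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    nd <- spec$n_drugs; nm <- spec$n_diseases; ng <- spec$n_genes
    drug_ids <- sprintf("DR%03d", seq_len(nd))
    disease_ids <- sprintf("DI%03d", seq_len(nm))
    gene_ids <- sprintf("G%04d", seq_len(ng))

    cd <- sort(rep_len(seq_len(spec$n_drug_clusters), nd))
    cs <- sort(rep_len(seq_len(spec$n_disease_clusters), nm))

    # compact per-cluster gene pools, disjoint per side, so within-cluster
    # gene overlap is strong and cross-cluster overlap is rare stray noise
    pool_size_d <- max(20L, min(30L, ng %/% (2L * spec$n_drug_clusters)))
    pool_size_s <- max(25L, min(40L, ng %/% (2L * spec$n_disease_clusters)))
    pool_d <- lapply(seq_len(spec$n_drug_clusters), function(i) {
      ((i - 1L) * pool_size_d + 1L):(i * pool_size_d)
    })
    pool_s <- lapply(seq_len(spec$n_disease_clusters), function(j) {
      ng - j * pool_size_s + seq_len(pool_size_s)
    })
    draw_genes <- function(pool, n_pick) {
      own <- sample(pool, min(n_pick, length(pool)))
      stray <- which(runif(ng) < 0.002)
      union(own, stray)
    }
    drug_gene <- matrix(0, nd, ng, dimnames = list(drug_ids, gene_ids))
    for (i in seq_len(nd)) {
      drug_gene[i, draw_genes(pool_d[[cd[i]]], sample(10:16, 1))] <- 1
    }
    dis_gene <- matrix(0, nm, ng, dimnames = list(disease_ids, gene_ids))
    for (j in seq_len(nm)) {
      dis_gene[j, draw_genes(pool_s[[cs[j]]], sample(10:20, 1))] <- 1
    }

    # known interactions: modular, confined to drug clusters
    ddi <- matrix(0, nd, nd, dimnames = list(drug_ids, drug_ids))
    for (i in seq_len(nd - 1)) {
      for (j in (i + 1):nd) {
        if (cd[i] == cd[j] && runif(1) < 0.15) ddi[i, j] <- ddi[j, i] <- 1
      }
    }

    # semantic similarity: cross-cluster pairs mostly unscored (zero)
    semantic <- matrix(0, nm, nm, dimnames = list(disease_ids, disease_ids))
    for (i in seq_len(nm - 1)) {
      for (j in (i + 1):nm) {
        v <- if (cs[i] == cs[j]) {
          stats::runif(1, 0.4, 0.9)
        } else if (runif(1) < 0.1) {
          stats::runif(1, 0, 0.15)
        } else 0
        semantic[i, j] <- semantic[j, i] <- v
      }
    }
    diag(semantic) <- 1

    fingerprints <- prototype_profiles(cd, spec$n_substructures,
                                       n_proto = min(120L, spec$n_substructures %/% 2L))
    dimnames(fingerprints) <- list(drug_ids,
                                   sprintf("sub%04d", seq_len(spec$n_substructures)))
    symptoms <- prototype_profiles(cs, spec$n_symptoms,
                                   n_proto = min(40L, spec$n_symptoms %/% 2L))
    dimnames(symptoms) <- list(disease_ids,
                               sprintf("sym%03d", seq_len(spec$n_symptoms)))

    # planted low-rank scores aligned with the clusters
    k <- spec$latent_rank
    loa_d <- matrix(runif(spec$n_drug_clusters * k, 0, 0.15),
                    spec$n_drug_clusters, k)
    for (i in seq_len(spec$n_drug_clusters)) {
      loa_d[i, (i - 1) %% k + 1] <- 1
    }
    loa_s <- matrix(runif(spec$n_disease_clusters * k, 0, 0.15),
                    spec$n_disease_clusters, k)
    for (j in seq_len(spec$n_disease_clusters)) {
      loa_s[j, (j - 1) %% k + 1] <- 1
      loa_s[j, (j + 1) %% k + 1] <- 0.6  # secondary factor couples the sides
    }
    u_star <- loa_d[cd, , drop = FALSE] * runif(nd, 0.6, 1) +
      matrix(runif(nd * k, 0, 0.05), nd, k)
    v_star <- t(loa_s[cs, , drop = FALSE] * runif(nm, 0.6, 1)) +
      matrix(runif(k * nm, 0, 0.05), k, nm)
    scores <- u_star %*% v_star
    n_ones <- round(spec$density * nd * nm)
    jitter <- matrix(runif(nd * nm, 0, 1e-9), nd, nm)  # deterministic tie-break
    cut <- sort(scores + jitter, decreasing = TRUE)[n_ones]
    Y <- matrix(as.integer(scores + jitter >= cut), nd, nm,
                dimnames = list(drug_ids, disease_ids))

    n_flip <- round(spec$noise * n_ones)
    if (n_flip > 0) {
      ones <- which(Y == 1)
      zeros <- which(Y == 0)
      drop_idx <- sample(ones, n_flip)
      add_idx <- sample(zeros, n_flip)
      Y[drop_idx] <- 0L
      Y[add_idx] <- 1L
    }

    structure(
      list(
        spec = spec, drug_ids = drug_ids, disease_ids = disease_ids,
        gene_ids = gene_ids, Y = Y, ddi = ddi, semantic = semantic,
        drug_gene = drug_gene, dis_gene = dis_gene,
        fingerprints = fingerprints, symptoms = symptoms,
        drug_clusters = tibble::tibble(entity_id = drug_ids, cluster = cd),
        disease_clusters = tibble::tibble(entity_id = disease_ids, cluster = cs),
        planted_scores = scores
      ),
      class = "drgcc_fixture"
    )
  })
}

#' Write a fixture bundle to plain-text files
#'
#' Emits every file format the pipeline consumes: edge lists for
#' associations, interactions and gene maps; dense TSV for the semantic
#' similarity, fingerprint incidence and symptom table; cluster label TSVs
#' and ID registries.
#'
#' @param bundle A `drgcc_fixture`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(bundle, dir) {
  stopifnot(inherits(bundle, "drgcc_fixture"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  mat_edges <- function(m, names_to) {
    idx <- which(m != 0, arr.ind = TRUE)
    out <- tibble::tibble(a = rownames(m)[idx[, 1]], b = colnames(m)[idx[, 2]])
    names(out) <- names_to
    out
  }
  write_edges_tsv(mat_edges(bundle$Y, c("drug_id", "disease_id")),
                  p("associations.tsv"))
  ddi_idx <- which(upper.tri(bundle$ddi) & bundle$ddi != 0, arr.ind = TRUE)
  write_edges_tsv(tibble::tibble(drug_a = rownames(bundle$ddi)[ddi_idx[, 1]],
                                 drug_b = colnames(bundle$ddi)[ddi_idx[, 2]]),
                  p("ddi.tsv"))
  write_edges_tsv(mat_edges(bundle$drug_gene, c("drug_id", "gene_id")),
                  p("drug_gene.tsv"))
  write_edges_tsv(mat_edges(bundle$dis_gene, c("disease_id", "gene_id")),
                  p("disease_gene.tsv"))
  write_matrix_tsv(bundle$semantic, p("semantic_similarity.tsv"))
  write_matrix_tsv(bundle$fingerprints, p("fingerprints.tsv"))
  write_matrix_tsv(bundle$symptoms, p("symptoms.tsv"))
  write_edges_tsv(bundle$drug_clusters, p("drug_clusters.tsv"))
  write_edges_tsv(bundle$disease_clusters, p("disease_clusters.tsv"))
  writeLines(bundle$drug_ids, p("drugs.txt"))
  writeLines(bundle$disease_ids, p("diseases.txt"))
  writeLines(bundle$gene_ids, p("genes.txt"))
  invisible(dir)
}

#' Read a fixture bundle written by [write_fixture()]
#'
#' @param dir Directory holding the files.
#' @return A `drgcc_fixture`-shaped list (without the generation spec).
#' @export
read_fixture <- function(dir) {
  p <- function(f) file.path(dir, f)
  drug_ids <- readLines(p("drugs.txt"))
  disease_ids <- readLines(p("diseases.txt"))
  gene_ids <- readLines(p("genes.txt"))
  assoc <- read_edges_tsv(p("associations.tsv"))
  Y <- matrix(0L, length(drug_ids), length(disease_ids),
              dimnames = list(drug_ids, disease_ids))
  Y[cbind(match(assoc$drug_id, drug_ids),
          match(assoc$disease_id, disease_ids))] <- 1L
  list(
    drug_ids = drug_ids, disease_ids = disease_ids, gene_ids = gene_ids,
    Y = Y,
    ddi = interaction_matrix(read_edges_tsv(p("ddi.tsv")), drug_ids),
    semantic = read_matrix_tsv(p("semantic_similarity.tsv")),
    drug_gene = incidence_matrix(read_edges_tsv(p("drug_gene.tsv")),
                                 drug_ids, gene_ids),
    dis_gene = incidence_matrix(read_edges_tsv(p("disease_gene.tsv")),
                                disease_ids, gene_ids),
    fingerprints = read_matrix_tsv(p("fingerprints.tsv")),
    symptoms = read_matrix_tsv(p("symptoms.tsv")),
    drug_clusters = read_edges_tsv(p("drug_clusters.tsv")),
    disease_clusters = read_edges_tsv(p("disease_clusters.tsv"))
  )
}
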