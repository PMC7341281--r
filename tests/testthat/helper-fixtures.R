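# Shared fixtures: small generator configurations, textbook pedigrees and a
# gene-dropping oracle for relationship coefficients.

tiny_config <- function(seed = 1L, ...) {
  args <- list(n_founders = 60L, n_generations = 5L,
               n_recorded_mares_target = 150L, sires_per_generation = 10L,
               eu_count = 4L, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}

small_config <- function(seed = 1L, ...) {
  args <- list(n_founders = 120L, n_generations = 7L,
               n_recorded_mares_target = 600L, sires_per_generation = 16L,
               seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}

# Textbook verification pedigrees ------------------------------------------

# 1,2 founders; 3,4 their full sibs; 5,6 offspring of the full-sib pair 3x4
ped_fullsib_mating <- data.frame(
  animal = 1:6,
  sire = c(0, 0, 1, 1, 3, 3),
  dam  = c(0, 0, 2, 2, 4, 4)
)

# 3 = offspring of sire 1 and his own daughter... parent-offspring mating
ped_parent_offspring <- data.frame(
  animal = 1:3,
  sire = c(0, 1, 1),
  dam  = c(0, 0, 2)
)

# shared sire, unrelated dams: 4 and 5 are paternal half sibs
ped_halfsib <- data.frame(
  animal = 1:5,
  sire = c(0, 0, 0, 1, 1),
  dam  = c(0, 0, 0, 2, 3)
)

# Random valid pedigree for property tests (generation-structured).
random_pedigree <- function(n_founders, n_per_gen, n_gen, seed) {
  set.seed(seed)
  ped <- data.frame(animal = seq_len(n_founders), sire = 0L, dam = 0L,
                    sex = rep(c("M", "F"), length.out = n_founders))
  for (g in seq_len(n_gen)) {
    males <- ped$animal[ped$sex == "M"]
    females <- ped$animal[ped$sex == "F"]
    ids <- max(ped$animal) + seq_len(n_per_gen)
    ped <- rbind(ped, data.frame(
      animal = ids,
      sire = sample(males, n_per_gen, replace = TRUE),
      dam = sample(females, n_per_gen, replace = TRUE),
      sex = sample(c("M", "F"), n_per_gen, replace = TRUE)))
  }
  ped
}

# Gene-dropping oracle -------------------------------------------------------
# Drops unique founder alleles through the pedigree `ndrop` times and
# estimates F (IBD of an animal's two alleles), the additive relationship
# (twice the kinship, i.e. average allele-pair IBD x 2) and the dominance
# relationship (probability the two animals carry the same unordered pair of
# parental alleles).
gene_drop <- function(pedigree, ndrop = 1e5, seed = 42) {
  set.seed(seed)
  n <- nrow(pedigree)
  id <- pedigree$animal
  si <- match(pedigree$sire, id, nomatch = 0L)
  di <- match(pedigree$dam, id, nomatch = 0L)
  pat <- mat <- vector("list", n)
  # founder alleles: unique id per founder allele, constant across drops
  allele_id <- 0L
  for (i in seq_len(n)) {
    if (si[i] == 0L) {
      pat[[i]] <- rep.int(allele_id + 1L, ndrop)
      allele_id <- allele_id + 1L
    } else {
      pick <- runif(ndrop) < 0.5
      pat[[i]] <- ifelse(pick, pat[[si[i]]], mat[[si[i]]])
    }
    if (di[i] == 0L) {
      mat[[i]] <- rep.int(allele_id + 1L, ndrop)
      allele_id <- allele_id + 1L
    } else {
      pick <- runif(ndrop) < 0.5
      mat[[i]] <- ifelse(pick, pat[[di[i]]], mat[[di[i]]])
    }
  }
  Fhat <- vapply(seq_len(n), function(i) mean(pat[[i]] == mat[[i]]),
                 numeric(1))
  Ahat <- matrix(0, n, n)
  Dhat <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in i:n) {
    k <- 0.25 * (mean(pat[[i]] == pat[[j]]) + mean(pat[[i]] == mat[[j]]) +
                   mean(mat[[i]] == pat[[j]]) + mean(mat[[i]] == mat[[j]]))
    Ahat[i, j] <- Ahat[j, i] <- 2 * k
    d <- mean((pat[[i]] == pat[[j]] & mat[[i]] == mat[[j]]) |
                (pat[[i]] == mat[[j]] & mat[[i]] == pat[[j]]))
    Dhat[i, j] <- Dhat[j, i] <- d
  }
  list(F = Fhat, A = Ahat, D = Dhat, ndrop = ndrop)
}
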