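---
title: "Out-of-core factorization of large genomic matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Out-of-core factorization of large genomic matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Genomic relationship matrices (GRMs) — the $N \times N$ symmetric
positive semi-definite matrices of pairwise genetic similarity that sit at
the heart of PCA, SNP-heritability estimation, linear mixed models and
genomic prediction — now outgrow the main memory of the machines most
analysts have. An $N = 100{,}000$ GRM alone is 40 GB in single precision,
and the divide-and-conquer eigensolver that factorizes it wants roughly a
further $2N^2$ floats of scratch workspace. The same applies to the tall
genotype matrices ($N$ individuals $\times$ $M$ markers, $N \gg M$) whose
thin SVD is the cheaper stand-in for a full GRM eigendecomposition.

`oocmatrix` factorizes such matrices *out of core*: every large array — the
input matrix, the eigenvector output, and the solver workspace — lives in a
file and is presented to the solver through POSIX `mmap`, so the operating
system pages data in and out as the algorithm touches it and the resident
footprint is bounded by available RAM rather than by $N^2$. The arithmetic
is unchanged; only the storage changes. That is the whole design: no
approximation, no truncation, the exact dense factorization on disk-resident
arrays.

## The model and the two routes

**Eigendecomposition.** For symmetric $A$ (the GRM) we compute
$A = Q \Lambda Q^{\mathsf T}$ with the divide-and-conquer symmetric driver
(`ssyevd`/`dsyevd`), called through LAPACK's middle-level interface in
which the caller supplies the workspace arrays. With eigenvectors
requested, that driver's documented minimum workspace is $1 + 6n + 2n^2$
floats plus $3 + 5n$ integers; `estimate_eigen_memory()` turns exactly this
into the package's closed-form memory model. In `mode = "disk"` the matrix
copy (factorized in place into $Q$), and both workspace arrays, are
`mmap`-ed files; in `mode = "memory"` they are ordinary allocations. Because
both modes execute the same LAPACK code path on the same bits, their results
agree to the last representable digit — the package tests this as a hard
invariant ("mode equivalence").

The selected-eigenpair driver (`ssyevr`-style) is deliberately not offered:
although it needs less workspace, its scattered workspace access pattern
interacts badly with paging, which is why the divide-and-conquer driver is
the right choice once arrays live on disk.

**SVD of tall matrices.** For $N \times M$ genotype matrices with
$N \gg M$ the package uses the Gram route: stream row tiles $B$ of $A$ and
accumulate $G = A^{\mathsf T} A = \sum B^{\mathsf T} B$ ($M \times M$, the
only piece that must be resident), eigendecompose $G$, set
$\sigma_i = \sqrt{\max(\lambda_i, 0)}$ descending with $V$ the paired
eigenvectors, then stream the rows again to form
$U_{\text{rows}} = B V \operatorname{diag}(1/\sigma)$. Forming
$A^{\mathsf T} A$ dominates the runtime, which is also why `svd_topk()`
(constrained to $k < \min(N, M)$) is barely faster than the full thin
decomposition: the Gram pass cannot be truncated.

The Gram route squares the condition number: $\sigma_i$ carries a relative
error on the order of $\varepsilon (\sigma_1/\sigma_i)^2$, so tiny singular
values are less accurate than a direct bidiagonalization would give. For
standardized genotype matrices, whose spectra are Marchenko–Pastur-shaped
and well conditioned, this is immaterial; it is the documented trade-off
that buys an $N$-free resident footprint.

## Parameters that matter

- **`precision`** (`"single"`/`"double"`): element type of storage *and*
  arithmetic. Single halves every footprint; the entire factorization then
  runs in IEEE-754 binary32, and eigenvalues typically agree with the
  double-precision result to a relative infinity norm of order
  $10 \varepsilon_{32} \approx 10^{-6}$ (measured by the test suite).
- **`tile_budget`** (elements, default $2^{26}$, i.e. 512 MiB of doubles):
  the cap on any streamed dense block. It affects I/O granularity only —
  `gram_accumulate()` results are tile-budget-independent up to
  $\varepsilon$-level summation reordering, another tested invariant.
- **`accumulation_precision`** (default `"double"`): the Gram accumulator's
  precision, kept at binary64 even for single-precision inputs because the
  accumulation of $N$ squared terms is where binary32 loses small
  $\sigma$; `"single"` is available to reproduce pure-binary32 pipelines.
- **rank tolerance**: $\sigma_i < \sqrt{\max(N, M)\,\varepsilon}\,\sigma_1$
  is treated as numerically zero; the corresponding $U$ columns are
  zero-filled and listed in `$zeroed` rather than divided by noise. The
  square root is forced by the Gram route: an exactly zero singular value
  surfaces as an eigenvalue of order $m\,\varepsilon\,\lambda_1$ in the
  accumulated $A^{\mathsf T} A$, i.e. at
  $\sigma \sim \sqrt{m\,\varepsilon}\,\sigma_1$ after the square root, so
  the linear-in-$\varepsilon$ tolerance a direct SVD would use cannot
  separate rank deficiency from accumulation noise here.
- **symmetry tolerance**: eigendecomposition rejects inputs whose
  off-diagonal mismatch exceeds $100\,\varepsilon \max|A|$ (sampled pairs
  for disk-resident inputs, exhaustive for in-memory ones). Repair is
  explicit (`symmetrize = TRUE`, tile-wise $(A + A^{\mathsf T})/2$), never
  silent, because an asymmetric "GRM" usually signals an upstream bug.
- **threads**: resolved as flag > `OOCMATRIX_NUM_THREADS` >
  `MKL_NUM_THREADS` (honored as an alias) > core count, and exported to the
  BLAS threading variables for child processes. BLAS libraries read those
  variables at load time, so the in-process effect depends on the backend;
  the resolved count is always logged.

## Numerical choices

Eigenvalues are returned ascending (the solver's convention; `descending =
TRUE` reverses values and vectors for PCA-style use). Sign of an
eigen/singular vector is arbitrary, so `V` columns are normalized to make
their largest-magnitude entry positive, and any comparison of vector
matrices goes through `align_signs()`, which flips a test column when its
inner product with the reference column is negative — the choice that
minimizes the Euclidean distance over all per-column sign assignments.
Comparisons themselves (`compare_vectors()`,
`compare_factorizations()`) report the three relative norms
$\lVert x_{\text{test}} - x_{\text{ref}}\rVert_p / \lVert x_{\text{ref}}\rVert_p$
for $p \in \{\infty, 1, 2\}$, normalized by the declared reference; columns
inside a degenerate eigenvalue cluster are reported as subspace-ambiguous
instead of being compared, because individual eigenvectors are not
identifiable there. Degenerate inputs behave boundary-completely: $1 \times
1$ matrices return themselves with $Q = [1]$, the zero matrix cannot anchor
a relative residual and says so.

Binary files are headerless raw IEEE-754, little-endian, row-major; the CLI
passes dimensions explicitly, which is the convention that makes a
headerless format usable, and row-major order is what row-block streaming
of tall matrices wants. Text output uses 9 (single) or 17 (double)
significant digits, the decimal precision that makes a text round trip
reproduce the stored binary exactly. LP64 LAPACK indexing caps the
disk-mode workspace at $2^{31} - 1$ elements, i.e. $n \lesssim 32{,}700$;
the guard raises a clear error rather than overflowing. Interoperability
with other tools' raw binary matrices is by convention only — a file
written column-major elsewhere must be transposed on import.

## What the synthetic generators emulate — and what they do not

`generate_genotypes()` draws marker $j$'s allele frequency $p_j \sim
U(\text{maf}_{\text{low}}, \text{maf}_{\text{high}})$ (default $[0.05,
0.5]$) and dosages $\sim \text{Binomial}(2, p_j)$ under Hardy–Weinberg
equilibrium: unrelated individuals, independent markers. `build_grm()` is
the field-standard (VanRaden) centered-and-scaled GRM,
$Z Z^{\mathsf T}/m$ with $Z$ column-standardized dosages, dropping
monomorphic markers. What this deliberately does *not* model: linkage
disequilibrium, population structure, relatedness, ascertainment — so
passing tests certify the numerics of the factorizations on matrices with
the right scale, symmetry, and spectral shape, not robustness to every
structure real cohorts exhibit. A real GRM is, to the solver, just another
dense symmetric PSD matrix, which is why this is the right level of realism
for a factorization library. Relatedness filtering (dropping pairs above a
kinship threshold) is intentionally out of scope: fixtures are unrelated by
construction. `build_grm()` assembles the $N \times N$ result in memory —
it is fixture plumbing for the factorizers, not itself an out-of-core
analysis.

## Problem sizes used by the tests

The invariant suite runs on fixtures up to $500$ individuals; the
cross-solver oracle checks (against base R's `eigen()`, which uses the
`dsyevr` driver, and `svd()`, which uses `dgesdd` — different algorithms
from the package's code path) run at dimension 200. The single-vs-double
agreement study uses GRMs built from $M = N$ markers at $N = 1000$ and $N =
10{,}000$: a marker panel of the order of the sample size keeps the full
Marchenko–Pastur-shaped spectrum while staying at desk scale, and the
measured agreement is insensitive to the $M/N$ ratio. These sizes are the
package's chosen reference conditions; everything scales up by changing the
arguments.

## Known limitations

- Disk mode relies on POSIX `mmap`; the package is Unix-only.
- The LP64 workspace cap above (double-precision in-memory mode shares it,
  since the same driver is used).
- The Gram route's squared-condition-number accuracy loss for
  $\sigma_i \ll \sigma_1$.
- Single-precision agreement constants are properties of the linked LAPACK
  implementation; different BLAS backends place the forward error at
  different small multiples of $\varepsilon_{32}$.
- `free_bytes()`-based pre-flight uses `df` and degrades to a no-op where
  unavailable.
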