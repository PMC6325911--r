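// Middle-level (FORTRAN-style, caller-supplied workspace) bindings to the
// divide-and-conquer symmetric eigensolvers SSYEVD/DSYEVD.  The caller
// provides the workspace arrays, which is what makes the out-of-core mode
// possible: in disk mode the matrix, the eigenvector output and the float
// workspace are all mmap()ed files, so resident memory is paging-bounded
// rather than O(n^2).
#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#include <R_ext/Lapack.h>
#ifndef FCONE
#define FCONE
#endif

#include <cerrno>
#include <cstring>
#include <string>
#include <vector>

#include <fcntl.h>
#include <sys/mman.h>
#include <sys/stat.h>
#include <unistd.h>

extern "C" {
// single-precision counterpart of dsyevd (declared in R_ext/Lapack.h)
void F77_NAME(ssyevd)(const char* jobz, const char* uplo, const int* n,
                      float* a, const int* lda, float* w, float* work,
                      const int* lwork, int* iwork, const int* liwork,
                      int* info FCLEN FCLEN);
}

using Rcpp::NumericMatrix;
using Rcpp::NumericVector;
using Rcpp::stop;

// LP64 LAPACK: workspace length must fit a 32-bit signed integer.
static int checked_lwork(double n) {
  double lw = 1.0 + 6.0 * n + 2.0 * n * n;
  if (lw > 2147483647.0)
    stop("matrix dimension %g needs a workspace of %g elements, beyond the 32-bit LAPACK index limit", n, lw);
  return (int)lw;
}

static void run_syevd_d(int n, double* a, double* w, double* work, int lwork,
                        int* iwork, int liwork) {
  int info = 0, lda = n;
  F77_CALL(dsyevd)("V", "L", &n, a, &lda, w, work, &lwork, iwork, &liwork,
                   &info FCONE FCONE);
  if (info != 0) stop("dsyevd failed to converge (info = %d)", info);
}

static void run_syevd_s(int n, float* a, float* w, float* work, int lwork,
                        int* iwork, int liwork) {
  int info = 0, lda = n;
  F77_CALL(ssyevd)("V", "L", &n, a, &lda, w, work, &lwork, iwork, &liwork,
                   &info FCONE FCONE);
  if (info != 0) stop("ssyevd failed to converge (info = %d)", info);
}

// In-memory eigendecomposition. `single = true` rounds the input to
// binary32 and runs the entire factorization in single precision.
// Eigenvalues ascending; eigenvectors in columns.
// [[Rcpp::export]]
Rcpp::List cpp_syevd_mem(NumericMatrix a, bool single) {
  int n = a.nrow();
  if (a.ncol() != n) stop("matrix must be square");
  int lwork = checked_lwork((double)n);
  int liwork = 3 + 5 * n;
  std::vector<int> iwork(liwork);
  NumericVector w(n);
  NumericMatrix q(n, n);
  if (single) {
    std::vector<float> af((size_t)n * n), wf(n), workf(lwork);
    for (size_t i = 0; i < af.size(); ++i) af[i] = (float)a[i];
    run_syevd_s(n, af.data(), wf.data(), workf.data(), lwork, iwork.data(),
                liwork);
    for (int i = 0; i < n; ++i) w[i] = (double)wf[i];
    for (size_t i = 0; i < af.size(); ++i) q[i] = (double)af[i];
  } else {
    std::vector<double> work(lwork);
    std::copy(a.begin(), a.end(), q.begin());
    run_syevd_d(n, &q[0], &w[0], work.data(), lwork, iwork.data(), liwork);
  }
  return Rcpp::List::create(Rcpp::Named("values") = w,
                            Rcpp::Named("vectors") = q);
}

namespace {
// RAII mmap of a whole file, created/grown on demand.
struct MappedFile {
  int fd = -1;
  void* ptr = MAP_FAILED;
  size_t bytes = 0;
  std::string path;

  void open_map(const std::string& p, size_t nbytes, bool create) {
    path = p;
    bytes = nbytes;
    fd = ::open(p.c_str(), create ? (O_RDWR | O_CREAT | O_TRUNC) : O_RDWR,
                0644);
    if (fd < 0)
      stop("cannot open '%s' for mapping: %s", p.c_str(), strerror(errno));
    if (create && ftruncate(fd, (off_t)nbytes) != 0) {
      int e = errno;
      ::close(fd);
      fd = -1;
      stop("cannot size workspace file '%s' to %.0f bytes: %s", p.c_str(),
           (double)nbytes, strerror(e));
    }
    ptr = ::mmap(NULL, nbytes, PROT_READ | PROT_WRITE, MAP_SHARED, fd, 0);
    if (ptr == MAP_FAILED) {
      int e = errno;
      ::close(fd);
      fd = -1;
      stop("mmap of '%s' (%.0f bytes) failed: %s", p.c_str(), (double)nbytes,
           strerror(e));
    }
  }

  ~MappedFile() {
    if (ptr != MAP_FAILED) ::munmap(ptr, bytes);
    if (fd >= 0) ::close(fd);
  }
};
}  // namespace

// Out-of-core eigendecomposition.  `a_path` holds the symmetric matrix
// (headerless raw binary, native little-endian, element size 4 or 8); it is
// factorized IN PLACE, so on return the file holds the eigenvectors in
// LAPACK column-major order (equivalently: one eigenvector per row-major
// row).  Workspace files are created at work_path / iwork_path and are the
// caller's to remove.  Returns the eigenvalues (ascending) as the only
// resident O(n) array.
// [[Rcpp::export]]
Rcpp::NumericVector cpp_syevd_disk(std::string a_path, double n_, bool single,
                                   std::string work_path,
                                   std::string iwork_path) {
  if (n_ < 1) stop("matrix dimension must be >= 1");
  int n = (int)n_;
  int lwork = checked_lwork(n_);
  int liwork = 3 + 5 * n;
  size_t es = single ? 4 : 8;

  MappedFile a, work, iw;
  a.open_map(a_path, (size_t)n * n * es, false);
  work.open_map(work_path, (size_t)lwork * es, true);
  iw.open_map(iwork_path, (size_t)liwork * sizeof(int), true);

  NumericVector w(n);
  if (single) {
    std::vector<float> wf(n);
    run_syevd_s(n, (float*)a.ptr, wf.data(), (float*)work.ptr, lwork,
                (int*)iw.ptr, liwork);
    for (int i = 0; i < n; ++i) w[i] = (double)wf[i];
  } else {
    run_syevd_d(n, (double*)a.ptr, &w[0], (double*)work.ptr, lwork,
                (int*)iw.ptr, liwork);
  }
  return w;
}

// Round each element through IEEE-754 binary32, the rounding a pure
// single-precision accumulation would apply after every operation block.
// [[Rcpp::export]]
Rcpp::NumericVector cpp_round_float(NumericVector x) {
  NumericVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) out[i] = (double)(float)x[i];
  return out;
}
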