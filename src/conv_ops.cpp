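// Single-precision branch engine for the convolutional streams.  Each
// branch owns a persistent workspace (float buffers behind an external
// pointer) sized for one mini-batch, so the training loop performs no
// large allocations; matrix products go to BLAS sgemm.  Single precision
// is the conventional arithmetic for CNN training; the package keeps a
// pure-R double-precision reference implementation of the same forward/
// backward pass for verification (see R/cnn-engine.R).
//
// Layout contract (shared with the R planner): tensors are flattened per
// sample as pos(h, w, c) = h + (w-1)*H + (c-1)*H*W; im2col index matrices
// idx (K x P) and pooling group index matrices gidx (g x Q) are 1-based
// into one sample block.  The ReLU is fused into max pooling
// (max(0, max(group)) == maxpool(relu(x))); clamped groups carry argmax 0
// and receive no gradient.

#include <Rcpp.h>
#include <cstring>
#include <vector>
using namespace Rcpp;

extern "C" void sgemm_(const char* transa, const char* transb, const int* m,
                       const int* n, const int* k, const float* alpha,
                       const float* a, const int* lda, const float* b,
                       const int* ldb, const float* beta, float* c,
                       const int* ldc, size_t, size_t);

static void sgemm(bool ta, bool tb, int m, int n, int k, const float* A,
                  int lda, const float* B, int ldb, float* C, int ldc) {
  const float one = 1.0f, zero = 0.0f;
  sgemm_(ta ? "T" : "N", tb ? "T" : "N", &m, &n, &k, &one, A, &lda, B, &ldb,
         &zero, C, &ldc, 1, 1);
}

struct BranchWS {
  int B;                       // mini-batch size
  int lenX;                    // flattened input length per sample
  int K1, P1, C1, Q1;          // stage-1 geometry
  int K2, P2, C2, Q2;          // stage-2 geometry
  std::vector<float> X, Xc1, A1, P1o, Xc2, A2, P2o;
  std::vector<float> dA2, G2, dX2, dA1, dFf;
  std::vector<int> amax1, amax2;
  std::vector<float> W1, b1, W2, b2;   // per-call float copies of weights
};

// [[Rcpp::export]]
SEXP cpp_branch_ws(const int B, const int lenX, const int K1, const int P1,
                   const int C1, const int Q1, const int K2, const int P2,
                   const int C2, const int Q2) {
  BranchWS* ws = new BranchWS();
  ws->B = B; ws->lenX = lenX;
  ws->K1 = K1; ws->P1 = P1; ws->C1 = C1; ws->Q1 = Q1;
  ws->K2 = K2; ws->P2 = P2; ws->C2 = C2; ws->Q2 = Q2;
  ws->X.resize((size_t)lenX * B);
  ws->Xc1.resize((size_t)K1 * P1 * B);
  ws->A1.resize((size_t)C1 * P1 * B);
  ws->P1o.resize((size_t)Q1 * B);
  ws->amax1.resize((size_t)Q1 * B);
  ws->Xc2.resize((size_t)K2 * P2 * B);
  ws->A2.resize((size_t)C2 * P2 * B);
  ws->P2o.resize((size_t)Q2 * B);
  ws->amax2.resize((size_t)Q2 * B);
  ws->dA2.resize((size_t)C2 * P2 * B);
  ws->G2.resize((size_t)K2 * P2 * B);
  ws->dX2.resize((size_t)Q1 * B);
  ws->dA1.resize((size_t)C1 * P1 * B);
  ws->dFf.resize((size_t)Q2 * B);
  ws->W1.resize((size_t)C1 * K1); ws->b1.resize(C1);
  ws->W2.resize((size_t)C2 * K2); ws->b2.resize(C2);
  XPtr<BranchWS> p(ws, true);
  return p;
}

static void im2colF(const float* X, const int* idx, const int K, const int P,
                    const int len, const int B, float* out) {
  for (int b = 0; b < B; ++b) {
    const float* xb = X + (size_t)b * len;
    float* ob = out + (size_t)b * K * P;
    for (size_t e = 0; e < (size_t)K * P; ++e) ob[e] = xb[idx[e] - 1];
  }
}

static void addBiasF(float* A, const float* b, const int m, const size_t n) {
  for (size_t j = 0; j < n; ++j, A += m)
    for (int i = 0; i < m; ++i) A[i] += b[i];
}

static void maxpoolF(const float* Y, const int* gidx, const int g,
                     const int Q, const int C, const int P, const int B,
                     float* out, int* amax) {
  const size_t S = (size_t)C * P;
  for (int b = 0; b < B; ++b) {
    const float* yb = Y + (size_t)b * S;
    float* ob = out + (size_t)b * Q;
    int* ab = amax + (size_t)b * Q;
    for (int q = 0; q < Q; ++q) {
      const int* col = gidx + (size_t)q * g;
      float best = yb[col[0] - 1];
      int besti = col[0];
      for (int e = 1; e < g; ++e) {
        const float v = yb[col[e] - 1];
        if (v > best) { best = v; besti = col[e]; }
      }
      if (best <= 0.0f) { best = 0.0f; besti = 0; }
      ob[q] = best;
      ab[q] = besti;
    }
  }
}

static void maxpoolBwdF(const float* dOut, const int* amax, const int Q,
                        const int C, const int P, const int B, float* out) {
  const size_t S = (size_t)C * P;
  std::memset(out, 0, sizeof(float) * S * B);
  for (int b = 0; b < B; ++b) {
    float* ob = out + b * S;
    const float* db = dOut + (size_t)b * Q;
    const int* ab = amax + (size_t)b * Q;
    for (int q = 0; q < Q; ++q)
      if (ab[q] > 0) ob[ab[q] - 1] += db[q];
  }
}

static void toF(const double* x, float* f, size_t n) {
  for (size_t i = 0; i < n; ++i) f[i] = (float)x[i];
}

// Forward pass of one branch; returns the flattened pooled features
// (Q2 x B) in double precision.  The workspace keeps every intermediate
// the backward pass needs.
// [[Rcpp::export]]
NumericMatrix cpp_branch_fwd(SEXP wsp, const NumericMatrix& X,
                             const IntegerMatrix& idx1,
                             const IntegerMatrix& gidx1,
                             const IntegerMatrix& idx2,
                             const IntegerMatrix& gidx2,
                             const NumericMatrix& W1,
                             const NumericVector& b1,
                             const NumericMatrix& W2,
                             const NumericVector& b2) {
  XPtr<BranchWS> ws(wsp);
  const int B = X.ncol();
  if (B != ws->B || X.nrow() != ws->lenX)
    stop("workspace does not match input dimensions");
  toF(X.begin(), ws->X.data(), (size_t)ws->lenX * B);
  toF(W1.begin(), ws->W1.data(), ws->W1.size());
  toF(b1.begin(), ws->b1.data(), ws->b1.size());
  toF(W2.begin(), ws->W2.data(), ws->W2.size());
  toF(b2.begin(), ws->b2.data(), ws->b2.size());
  im2colF(ws->X.data(), idx1.begin(), ws->K1, ws->P1, ws->lenX, B,
          ws->Xc1.data());
  sgemm(false, false, ws->C1, ws->P1 * B, ws->K1, ws->W1.data(), ws->C1,
        ws->Xc1.data(), ws->K1, ws->A1.data(), ws->C1);
  addBiasF(ws->A1.data(), ws->b1.data(), ws->C1, (size_t)ws->P1 * B);
  maxpoolF(ws->A1.data(), gidx1.begin(), gidx1.nrow(), ws->Q1, ws->C1,
           ws->P1, B, ws->P1o.data(), ws->amax1.data());
  im2colF(ws->P1o.data(), idx2.begin(), ws->K2, ws->P2, ws->Q1, B,
          ws->Xc2.data());
  sgemm(false, false, ws->C2, ws->P2 * B, ws->K2, ws->W2.data(), ws->C2,
        ws->Xc2.data(), ws->K2, ws->A2.data(), ws->C2);
  addBiasF(ws->A2.data(), ws->b2.data(), ws->C2, (size_t)ws->P2 * B);
  maxpoolF(ws->A2.data(), gidx2.begin(), gidx2.nrow(), ws->Q2, ws->C2,
           ws->P2, B, ws->P2o.data(), ws->amax2.data());
  NumericMatrix out(ws->Q2, B);
  double* op = out.begin();
  const float* pp = ws->P2o.data();
  for (size_t i = 0; i < (size_t)ws->Q2 * B; ++i) op[i] = pp[i];
  return out;
}

// Backward pass from dF (Q2 x B); must follow a forward pass on the same
// workspace.  Returns the weight/bias gradients in double precision.
// [[Rcpp::export]]
List cpp_branch_bwd(SEXP wsp, const NumericMatrix& dF,
                    const IntegerMatrix& idx2, const NumericMatrix& W2) {
  XPtr<BranchWS> ws(wsp);
  const int B = dF.ncol();
  if (B != ws->B || dF.nrow() != ws->Q2)
    stop("workspace does not match gradient dimensions");
  toF(dF.begin(), ws->dFf.data(), (size_t)ws->Q2 * B);
  maxpoolBwdF(ws->dFf.data(), ws->amax2.data(), ws->Q2, ws->C2, ws->P2, B,
              ws->dA2.data());
  // dW2 = dA2 %*% t(Xc2), db2 = rowSums(dA2)
  std::vector<float> dW2f((size_t)ws->C2 * ws->K2);
  sgemm(false, true, ws->C2, ws->K2, ws->P2 * B, ws->dA2.data(), ws->C2,
        ws->Xc2.data(), ws->K2, dW2f.data(), ws->C2);
  NumericVector db2(ws->C2);
  {
    const float* p = ws->dA2.data();
    for (size_t j = 0; j < (size_t)ws->P2 * B; ++j, p += ws->C2)
      for (int i = 0; i < ws->C2; ++i) db2[i] += p[i];
  }
  // G2 = t(W2) %*% dA2 -> col2im -> dX2 -> pool1 backward -> dA1
  toF(W2.begin(), ws->W2.data(), ws->W2.size());
  sgemm(true, false, ws->K2, ws->P2 * B, ws->C2, ws->W2.data(), ws->C2,
        ws->dA2.data(), ws->C2, ws->G2.data(), ws->K2);
  {
    std::memset(ws->dX2.data(), 0, sizeof(float) * (size_t)ws->Q1 * B);
    const int* ip = idx2.begin();
    for (int b = 0; b < B; ++b) {
      const float* gb = ws->G2.data() + (size_t)b * ws->K2 * ws->P2;
      float* ob = ws->dX2.data() + (size_t)b * ws->Q1;
      for (size_t e = 0; e < (size_t)ws->K2 * ws->P2; ++e)
        ob[ip[e] - 1] += gb[e];
    }
  }
  maxpoolBwdF(ws->dX2.data(), ws->amax1.data(), ws->Q1, ws->C1, ws->P1, B,
              ws->dA1.data());
  std::vector<float> dW1f((size_t)ws->C1 * ws->K1);
  sgemm(false, true, ws->C1, ws->K1, ws->P1 * B, ws->dA1.data(), ws->C1,
        ws->Xc1.data(), ws->K1, dW1f.data(), ws->C1);
  NumericVector db1(ws->C1);
  {
    const float* p = ws->dA1.data();
    for (size_t j = 0; j < (size_t)ws->P1 * B; ++j, p += ws->C1)
      for (int i = 0; i < ws->C1; ++i) db1[i] += p[i];
  }
  NumericMatrix dW1(ws->C1, ws->K1), dW2(ws->C2, ws->K2);
  for (size_t i = 0; i < dW1f.size(); ++i) dW1.begin()[i] = dW1f[i];
  for (size_t i = 0; i < dW2f.size(); ++i) dW2.begin()[i] = dW2f[i];
  return List::create(_["W1"] = dW1, _["b1"] = db1, _["W2"] = dW2,
                      _["b2"] = db2);
}
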