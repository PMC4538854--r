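// Voxel finite-element kernels: trilinear hexahedral elements on a regular
// lattice, one element per voxel, with Dirichlet (u = 0) window boundaries.
// The stiffness integrates C = lambda*(e e') + mu*diag(2,2,2,1,1,1) (Voigt,
// engineering shears), so K_e = h * (lambda*Kl + mu*Km) with Kl, Km computed
// once on the unit cube by 2x2x2 Gauss quadrature.
#include <Rcpp.h>
#include <vector>
#include <queue>
#include <algorithm>
#include <cmath>
#include <cstring>
using namespace Rcpp;

namespace {

struct Hex8 {
  double Kl[24][24];
  double Km[24][24];
  double load[24][3];  // f = -integral B' sigma0 dV for unit sigma on each axis, unit cube
  double Bc[3][24];    // centroid axial-strain rows (unit cube): eps_i = Bc[i] . u_e
  bool ready = false;
};

Hex8 hexdata;

// shape derivative of node a wrt natural coords at (xi, eta, ze); nodes
// ordered x fastest: a = di + 2*dj + 4*dk, di,dj,dk in {0,1}
inline void shape_deriv(int a, double xi, double eta, double ze, double g[3]) {
  int di = a & 1, dj = (a >> 1) & 1, dk = (a >> 2) & 1;
  double sx = di ? 1.0 : -1.0, sy = dj ? 1.0 : -1.0, sz = dk ? 1.0 : -1.0;
  double fx = 0.5 * (1.0 + sx * xi), fy = 0.5 * (1.0 + sy * eta), fz = 0.5 * (1.0 + sz * ze);
  g[0] = 0.5 * sx * fy * fz;
  g[1] = fx * 0.5 * sy * fz;
  g[2] = fx * fy * 0.5 * sz;
}

void init_hex8() {
  if (hexdata.ready) return;
  std::memset(hexdata.Kl, 0, sizeof(hexdata.Kl));
  std::memset(hexdata.Km, 0, sizeof(hexdata.Km));
  std::memset(hexdata.load, 0, sizeof(hexdata.load));
  std::memset(hexdata.Bc, 0, sizeof(hexdata.Bc));
  const double gp = 1.0 / std::sqrt(3.0);
  // unit cube: x = (xi+1)/2 -> dN/dx = 2 * dN/dxi, detJ = 1/8
  for (int gx = 0; gx < 2; ++gx) for (int gy = 0; gy < 2; ++gy) for (int gz = 0; gz < 2; ++gz) {
    double xi = gx ? gp : -gp, eta = gy ? gp : -gp, ze = gz ? gp : -gp;
    double dN[8][3];
    for (int a = 0; a < 8; ++a) {
      double g[3];
      shape_deriv(a, xi, eta, ze, g);
      for (int d = 0; d < 3; ++d) dN[a][d] = 2.0 * g[d];
    }
    // B is 6x24: rows exx eyy ezz gxy gyz gzx
    double B[6][24];
    std::memset(B, 0, sizeof(B));
    for (int a = 0; a < 8; ++a) {
      int c = 3 * a;
      B[0][c + 0] = dN[a][0];
      B[1][c + 1] = dN[a][1];
      B[2][c + 2] = dN[a][2];
      B[3][c + 0] = dN[a][1]; B[3][c + 1] = dN[a][0];
      B[4][c + 1] = dN[a][2]; B[4][c + 2] = dN[a][1];
      B[5][c + 0] = dN[a][2]; B[5][c + 2] = dN[a][0];
    }
    const double w = 1.0 / 8.0;  // detJ * gauss weight (1) on unit cube
    for (int p = 0; p < 24; ++p) for (int q = 0; q < 24; ++q) {
      double vl = (B[0][p] + B[1][p] + B[2][p]) * (B[0][q] + B[1][q] + B[2][q]);
      double vm = 2.0 * (B[0][p] * B[0][q] + B[1][p] * B[1][q] + B[2][p] * B[2][q])
                + B[3][p] * B[3][q] + B[4][p] * B[4][q] + B[5][p] * B[5][q];
      hexdata.Kl[p][q] += w * vl;
      hexdata.Km[p][q] += w * vm;
    }
    // load for unit axial prestress on each axis: f_p = -int B'[p][axis-row]
    for (int p = 0; p < 24; ++p) for (int ax = 0; ax < 3; ++ax)
      hexdata.load[p][ax] -= w * B[ax][p];
  }
  // centroid strain rows
  double g[3];
  for (int a = 0; a < 8; ++a) {
    shape_deriv(a, 0.0, 0.0, 0.0, g);
    for (int d = 0; d < 3; ++d) hexdata.Bc[d][3 * a + d] = 2.0 * g[d];
  }
  hexdata.ready = true;
}

struct FEProblem {
  int nx, ny, nz;
  double h;
  int nnodes, ndof;
  std::vector<int> dof;        // nnodes*3 -> dof id or -1
  std::vector<int> actelem;    // active element linear indices (x fastest)
  std::vector<int> elemnodes;  // 8 node ids per active element
  std::vector<int> rowptr, colind;
  std::vector<double> val, diag;
  // Jacobi-scaled strict lower triangle (for the Eisenstat solver)
  std::vector<int> lrowptr, lcolind;
  std::vector<double> lval, sc;
};

inline int node_id(const FEProblem& P, int i, int j, int k) {
  return (k * (P.ny + 1) + j) * (P.nx + 1) + i;
}

void csr_matvec(const FEProblem& P, const double* x, double* y) {
  const int n = P.ndof;
  for (int r = 0; r < n; ++r) {
    double s = 0.0;
    for (int idx = P.rowptr[r]; idx < P.rowptr[r + 1]; ++idx)
      s += P.val[idx] * x[P.colind[idx]];
    y[r] = s;
  }
}

}  // namespace

typedef Rcpp::XPtr<FEProblem> FEPtr;

// [[Rcpp::export(name = ".vm_fe_setup")]]
SEXP vm_fe_setup(int nx, int ny, int nz, double h, LogicalVector active) {
  init_hex8();
  FEProblem* P = new FEProblem();
  P->nx = nx; P->ny = ny; P->nz = nz; P->h = h;
  P->nnodes = (nx + 1) * (ny + 1) * (nz + 1);
  const int nelem = nx * ny * nz;
  if (active.size() != nelem) stop("active mask length mismatch");
  // collect active elements and their nodes
  std::vector<char> node_touch(P->nnodes, 0);
  for (int k = 0; k < nz; ++k) for (int j = 0; j < ny; ++j) for (int i = 0; i < nx; ++i) {
    int e = (k * ny + j) * nx + i;
    if (!active[e]) continue;
    P->actelem.push_back(e);
    for (int dk = 0; dk < 2; ++dk) for (int dj = 0; dj < 2; ++dj) for (int di = 0; di < 2; ++di) {
      int nid = node_id(*P, i + di, j + dj, k + dk);
      P->elemnodes.push_back(nid);
      node_touch[nid] = 1;
    }
  }
  // dof numbering: interior nodes touching at least one active element
  P->dof.assign(P->nnodes * 3, -1);
  int nd = 0;
  for (int k = 0; k <= nz; ++k) for (int j = 0; j <= ny; ++j) for (int i = 0; i <= nx; ++i) {
    int nid = node_id(*P, i, j, k);
    bool boundary = (i == 0 || i == nx || j == 0 || j == ny || k == 0 || k == nz);
    if (!boundary && node_touch[nid]) {
      for (int d = 0; d < 3; ++d) P->dof[3 * nid + d] = nd++;
    }
  }
  P->ndof = nd;
  // CSR pattern from node adjacency
  std::vector<std::vector<int>> adj(nd);
  const int nact = (int)P->actelem.size();
  for (int ea = 0; ea < nact; ++ea) {
    const int* nn = &P->elemnodes[8 * ea];
    for (int a = 0; a < 8; ++a) for (int da = 0; da < 3; ++da) {
      int ra = P->dof[3 * nn[a] + da];
      if (ra < 0) continue;
      for (int b = 0; b < 8; ++b) for (int db = 0; db < 3; ++db) {
        int cb = P->dof[3 * nn[b] + db];
        if (cb >= 0) adj[ra].push_back(cb);
      }
    }
  }
  P->rowptr.assign(nd + 1, 0);
  size_t nnz = 0;
  for (int r = 0; r < nd; ++r) {
    std::sort(adj[r].begin(), adj[r].end());
    adj[r].erase(std::unique(adj[r].begin(), adj[r].end()), adj[r].end());
    nnz += adj[r].size();
    P->rowptr[r + 1] = (int)nnz;
  }
  P->colind.resize(nnz);
  for (int r = 0; r < nd; ++r)
    std::copy(adj[r].begin(), adj[r].end(), P->colind.begin() + P->rowptr[r]);
  P->val.assign(nnz, 0.0);
  P->diag.assign(nd, 0.0);
  return FEPtr(P, true);
}

// [[Rcpp::export(name = ".vm_fe_ndof")]]
int vm_fe_ndof(SEXP ptr) { return FEPtr(ptr)->ndof; }

// lam, mu: per full-grid element (Lame parameters, kPa); only active used
// [[Rcpp::export(name = ".vm_fe_assemble")]]
void vm_fe_assemble(SEXP ptr, NumericVector lam, NumericVector mu) {
  FEPtr P(ptr);
  init_hex8();
  std::fill(P->val.begin(), P->val.end(), 0.0);
  const int nact = (int)P->actelem.size();
  for (int ea = 0; ea < nact; ++ea) {
    int e = P->actelem[ea];
    double la = lam[e] * P->h, mua = mu[e] * P->h;
    const int* nn = &P->elemnodes[8 * ea];
    int rdof[24];
    for (int a = 0; a < 8; ++a) for (int d = 0; d < 3; ++d)
      rdof[3 * a + d] = P->dof[3 * nn[a] + d];
    for (int p = 0; p < 24; ++p) {
      int r = rdof[p];
      if (r < 0) continue;
      const int lo = P->rowptr[r], hi = P->rowptr[r + 1];
      for (int q = 0; q < 24; ++q) {
        int c = rdof[q];
        if (c < 0) continue;
        double v = la * hexdata.Kl[p][q] + mua * hexdata.Km[p][q];
        // binary search for column c in row r
        const int* base = P->colind.data();
        const int* pos = std::lower_bound(base + lo, base + hi, c);
        P->val[pos - base] += v;
      }
    }
  }
  for (int r = 0; r < P->ndof; ++r) {
    for (int idx = P->rowptr[r]; idx < P->rowptr[r + 1]; ++idx)
      if (P->colind[idx] == r) { P->diag[r] = P->val[idx]; break; }
    if (P->diag[r] <= 0.0) P->diag[r] = 1.0;  // safeguarded (isolated dof)
  }
  // prescaled strict lower triangle for the solver
  const int n = P->ndof;
  P->sc.resize(n);
  for (int i = 0; i < n; ++i) P->sc[i] = 1.0 / std::sqrt(P->diag[i]);
  if (P->lrowptr.empty()) {
    P->lrowptr.assign(n + 1, 0);
    size_t lnnz = 0;
    for (int i = 0; i < n; ++i) {
      for (int idx = P->rowptr[i]; idx < P->rowptr[i + 1]; ++idx)
        if (P->colind[idx] < i) ++lnnz;
      P->lrowptr[i + 1] = (int)lnnz;
    }
    P->lcolind.resize(lnnz);
    P->lval.resize(lnnz);
    size_t k = 0;
    for (int i = 0; i < n; ++i)
      for (int idx = P->rowptr[i]; idx < P->rowptr[i + 1]; ++idx)
        if (P->colind[idx] < i) P->lcolind[k++] = P->colind[idx];
  }
  size_t k = 0;
  for (int i = 0; i < n; ++i)
    for (int idx = P->rowptr[i]; idx < P->rowptr[i + 1]; ++idx)
      if (P->colind[idx] < i)
        P->lval[k++] = P->sc[i] * P->val[idx] * P->sc[P->colind[idx]];
}

// sig: nelem x 3 active prestress (kPa); returns load vector f (ndof)
// [[Rcpp::export(name = ".vm_fe_load")]]
NumericVector vm_fe_load(SEXP ptr, NumericMatrix sig) {
  FEPtr P(ptr);
  init_hex8();
  NumericVector f(P->ndof);
  const int nact = (int)P->actelem.size();
  const double h2 = P->h * P->h;
  for (int ea = 0; ea < nact; ++ea) {
    int e = P->actelem[ea];
    double sx = sig(e, 0), sy = sig(e, 1), sz = sig(e, 2);
    if (sx == 0.0 && sy == 0.0 && sz == 0.0) continue;
    const int* nn = &P->elemnodes[8 * ea];
    for (int a = 0; a < 8; ++a) for (int d = 0; d < 3; ++d) {
      int r = P->dof[3 * nn[a] + d];
      if (r < 0) continue;
      double s = (d == 0) ? sx : (d == 1 ? sy : sz);
      f[r] += h2 * hexdata.load[3 * a + d][d] * s;
    }
  }
  return f;
}

namespace {

// Sweeps on the symmetrically scaled matrix Abar = S A S (unit diagonal),
// using the prescaled strict lower triangle Lbar; Ubar = Lbar'.

// forward solve (I/w + Lbar) t = r
void lower_solve_sc(const FEProblem& P, double omega, const double* r,
                    double* t) {
  const int n = P.ndof;
  for (int i = 0; i < n; ++i) {
    double s = r[i];
    for (int idx = P.lrowptr[i]; idx < P.lrowptr[i + 1]; ++idx)
      s -= P.lval[idx] * t[P.lcolind[idx]];
    t[i] = s * omega;
  }
}

// backward solve (I/w + Ubar) t = r, via column scatter of Lbar
void upper_solve_sc(const FEProblem& P, double omega, const double* r,
                    double* t, std::vector<double>& wk) {
  const int n = P.ndof;
  std::copy(r, r + n, wk.begin());
  for (int i = n - 1; i >= 0; --i) {
    const double ti = wk[i] * omega;
    t[i] = ti;
    for (int idx = P.lrowptr[i]; idx < P.lrowptr[i + 1]; ++idx)
      wk[P.lcolind[idx]] -= P.lval[idx] * ti;
  }
}

// y = (I/w + Ubar) x, via column gather of Lbar
void upper_matvec_sc(const FEProblem& P, double omega, const double* x,
                     double* y) {
  const int n = P.ndof;
  for (int i = 0; i < n; ++i) y[i] = x[i] / omega;
  for (int i = 0; i < n; ++i) {
    const double xi = x[i];
    for (int idx = P.lrowptr[i]; idx < P.lrowptr[i + 1]; ++idx)
      y[P.lcolind[idx]] += P.lval[idx] * xi;
  }
}

}  // namespace

// SSOR-preconditioned CG via Eisenstat's trick on the Jacobi-scaled system:
// CG runs on M1^-1 Abar M2^-1 (M1 = I/w + Lbar, M2 = M1'), so an iteration
// costs one forward plus one backward sweep instead of a matvec plus both
// sweeps. The reported relres is the true residual of A x = f.
// [[Rcpp::export(name = ".vm_fe_solve")]]
List vm_fe_solve(SEXP ptr, NumericVector f, NumericVector u0,
                 double rtol, int maxit, double omega) {
  FEPtr P(ptr);
  const int n = P->ndof;
  double bnorm = 0.0;
  for (int i = 0; i < n; ++i) bnorm += f[i] * f[i];
  bnorm = std::sqrt(bnorm);
  if (bnorm == 0.0) {
    NumericVector u(n);
    return List::create(_["u"] = u, _["iters"] = 0, _["relres"] = 0.0);
  }
  const double* sc = P->sc.data();
  const double dh = (2.0 - omega) / omega;  // scaled Dh is constant
  std::vector<double> y(n), r(n), p(n), Ap(n), t(n), w(n), x(n), wk(n);
  // scaled variables: xbar = S^-1 x, fbar = S f
  bool warm = (u0.size() == n);
  for (int i = 0; i < n; ++i) x[i] = warm ? u0[i] / sc[i] : 0.0;
  upper_matvec_sc(*P, omega, x.data(), y.data());
  // rhat = M1^-1 (fbar - Abar xbar); Abar xbar computed via A (S xbar)
  for (int i = 0; i < n; ++i) w[i] = sc[i] * x[i];
  csr_matvec(*P, w.data(), Ap.data());
  for (int i = 0; i < n; ++i) w[i] = sc[i] * f[i] - sc[i] * Ap[i];
  lower_solve_sc(*P, omega, w.data(), r.data());
  for (int i = 0; i < n; ++i) w[i] = sc[i] * f[i];
  lower_solve_sc(*P, omega, w.data(), t.data());
  double bhat = 0.0;
  for (int i = 0; i < n; ++i) bhat += t[i] * t[i];
  bhat = std::sqrt(bhat);
  if (bhat == 0.0) bhat = 1.0;
  double rz = 0.0;
  for (int i = 0; i < n; ++i) rz += r[i] * r[i];
  double rnorm = std::sqrt(rz);
  std::copy(r.begin(), r.end(), p.begin());
  int it = 0;
  while (rnorm / bhat > rtol && it < maxit) {
    // Ahat p = M2^-1 p + M1^-1 (p - dh * M2^-1 p)
    upper_solve_sc(*P, omega, p.data(), t.data(), wk);
    for (int i = 0; i < n; ++i) w[i] = p[i] - dh * t[i];
    lower_solve_sc(*P, omega, w.data(), Ap.data());
    for (int i = 0; i < n; ++i) Ap[i] += t[i];
    double pAp = 0.0;
    for (int i = 0; i < n; ++i) pAp += p[i] * Ap[i];
    if (pAp <= 0.0) break;
    double alpha = rz / pAp;
    double rznew = 0.0;
    for (int i = 0; i < n; ++i) {
      y[i] += alpha * p[i];
      r[i] -= alpha * Ap[i];
      rznew += r[i] * r[i];
    }
    rnorm = std::sqrt(rznew);
    double beta = rznew / rz;
    rz = rznew;
    for (int i = 0; i < n; ++i) p[i] = r[i] + beta * p[i];
    ++it;
  }
  // back-transform (xbar = M2^-1 y, x = S xbar) and report true residual
  upper_solve_sc(*P, omega, y.data(), x.data(), wk);
  NumericVector u(n);
  for (int i = 0; i < n; ++i) u[i] = sc[i] * x[i];
  csr_matvec(*P, &u[0], Ap.data());
  double tr = 0.0;
  for (int i = 0; i < n; ++i) {
    double d = f[i] - Ap[i];
    tr += d * d;
  }
  return List::create(_["u"] = u, _["iters"] = it,
                      _["relres"] = std::sqrt(tr) / bnorm);
}

// centroid axial strains for the given full-grid element indices (1-based)
// [[Rcpp::export(name = ".vm_fe_strains")]]
NumericMatrix vm_fe_strains(SEXP ptr, NumericVector u, IntegerVector elems) {
  FEPtr P(ptr);
  init_hex8();
  const int ne = elems.size();
  NumericMatrix eps(ne, 3);
  // map full-grid element id -> active slot
  std::vector<int> slot(P->nx * P->ny * P->nz, -1);
  for (int ea = 0; ea < (int)P->actelem.size(); ++ea) slot[P->actelem[ea]] = ea;
  for (int m = 0; m < ne; ++m) {
    int e = elems[m] - 1;
    int ea = slot[e];
    if (ea < 0) { eps(m, 0) = eps(m, 1) = eps(m, 2) = NA_REAL; continue; }
    const int* nn = &P->elemnodes[8 * ea];
    double ue[24];
    for (int a = 0; a < 8; ++a) for (int d = 0; d < 3; ++d) {
      int r = P->dof[3 * nn[a] + d];
      ue[3 * a + d] = (r >= 0) ? u[r] : 0.0;
    }
    for (int d = 0; d < 3; ++d) {
      double s = 0.0;
      for (int q = 0; q < 24; ++q) s += hexdata.Bc[d][q] * ue[q];
      eps(m, d) = s / P->h;
    }
  }
  return eps;
}

// expand active-dof vector to (nnodes x 3) displacement matrix
// [[Rcpp::export(name = ".vm_fe_expand")]]
NumericMatrix vm_fe_expand(SEXP ptr, NumericVector u) {
  FEPtr P(ptr);
  NumericMatrix U(P->nnodes, 3);
  for (int nid = 0; nid < P->nnodes; ++nid)
    for (int d = 0; d < 3; ++d) {
      int r = P->dof[3 * nid + d];
      U(nid, d) = (r >= 0) ? u[r] : 0.0;
    }
  return U;
}

// 6-connected component of `member` voxels containing any of `seeds`
// (1-based linear indices, x fastest); returns logical membership
// [[Rcpp::export(name = ".vm_component")]]
LogicalVector vm_component(int nx, int ny, int nz, IntegerVector member,
                           IntegerVector seeds) {
  const int n = nx * ny * nz;
  std::vector<char> inset(n, 0), vis(n, 0);
  for (int m = 0; m < member.size(); ++m) inset[member[m] - 1] = 1;
  std::queue<int> q;
  for (int s = 0; s < seeds.size(); ++s) {
    int v = seeds[s] - 1;
    if (v >= 0 && v < n && inset[v] && !vis[v]) { vis[v] = 1; q.push(v); }
  }
  const int dx[6] = {1, -1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, 1, -1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, 1, -1};
  while (!q.empty()) {
    int v = q.front(); q.pop();
    int i = v % nx, j = (v / nx) % ny, k = v / (nx * ny);
    for (int d = 0; d < 6; ++d) {
      int ii = i + dx[d], jj = j + dy[d], kk = k + dz[d];
      if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
      int w = (kk * ny + jj) * nx + ii;
      if (inset[w] && !vis[w]) { vis[w] = 1; q.push(w); }
    }
  }
  LogicalVector out(n);
  for (int v = 0; v < n; ++v) out[v] = (vis[v] != 0);
  return out;
}
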