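#include <Rcpp.h>
using namespace Rcpp;

static inline void cross3(const double*a,const double*b,double*o){
  o[0]=a[1]*b[2]-a[2]*b[1]; o[1]=a[2]*b[0]-a[0]*b[2]; o[2]=a[0]*b[1]-a[1]*b[0];
}
static inline double norm3(const double*a){return sqrt(a[0]*a[0]+a[1]*a[1]+a[2]*a[2]);}

static void place(const double*a,const double*b,const double*c,
                  double bond,double ang_deg,double tor_deg,double*d){
  const double DEG = M_PI/180.0;
  double ang=ang_deg*DEG, tor=tor_deg*DEG;
  double bc[3], ab[3], n[3], m[3];
  for(int k=0;k<3;k++){ bc[k]=c[k]-b[k]; ab[k]=b[k]-a[k]; }
  double nb=norm3(bc); for(int k=0;k<3;k++) bc[k]/=nb;
  cross3(ab,bc,n); double nn=norm3(n); for(int k=0;k<3;k++) n[k]/=nn;
  cross3(n,bc,m);
  double d2[3]={-bond*cos(ang), bond*sin(ang)*cos(tor), bond*sin(ang)*sin(tor)};
  for(int k=0;k<3;k++) d[k]=c[k]+d2[0]*bc[k]+d2[1]*m[k]+d2[2]*n[k];
}

// [[Rcpp::export]]
NumericMatrix cpp_build_backbone(NumericVector phi, NumericVector psi){
  int n=phi.size();
  NumericMatrix out(4*n,3); // rows: N,CA,C,O per residue
  const double bNCA=1.458,bCAC=1.525,bCN=1.329,bCO=1.231;
  const double aNCAC=111.2,aCACN=116.2,aCNCA=121.7,aCACO=120.5;
  const double DEG=M_PI/180.0;
  double N[3]={0,0,0}, CA[3]={bNCA,0,0};
  double C[3]={bNCA+bCAC*(-cos(aNCAC*DEG)), bCAC*sin(aNCAC*DEG), 0};
  double pN[3],pCA[3],pC[3];
  for(int i=0;i<n;i++){
    if(i>0){
      for(int k=0;k<3;k++){pN[k]=N[k];pCA[k]=CA[k];pC[k]=C[k];}
      place(pN,pCA,pC,bCN,aCACN,psi[i-1],N);
      place(pCA,pC,N,bNCA,aCNCA,180.0,CA);
      place(pC,N,CA,bCAC,aNCAC,phi[i],C);
    }
    double O[3];
    place(N,CA,C,bCO,aCACO,psi[i]+180.0,O);
    for(int k=0;k<3;k++){
      out(4*i+0,k)=N[k]; out(4*i+1,k)=CA[k]; out(4*i+2,k)=C[k]; out(4*i+3,k)=O[k];
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_bb_score(NumericMatrix xyz, int nres, double soft_floor){
  // radius of gyration over CA + clash penalty over non-bonded heavy pairs
  double cx=0,cy=0,cz=0;
  for(int i=0;i<nres;i++){cx+=xyz(4*i+1,0);cy+=xyz(4*i+1,1);cz+=xyz(4*i+1,2);}
  cx/=nres;cy/=nres;cz/=nres;
  double rg=0;
  for(int i=0;i<nres;i++){
    double dx=xyz(4*i+1,0)-cx,dy=xyz(4*i+1,1)-cy,dz=xyz(4*i+1,2)-cz;
    rg+=dx*dx+dy*dy+dz*dz;
  }
  rg=sqrt(rg/nres);
  int na=4*nres;
  double pen=0, mind=1e9;
  for(int i=0;i<na;i++){
    int ri=i/4;
    for(int j=i+1;j<na;j++){
      int rj=j/4;
      if(rj-ri<=1) continue;
      double dx=xyz(i,0)-xyz(j,0); if(fabs(dx)>soft_floor) continue;
      double dy=xyz(i,1)-xyz(j,1); if(fabs(dy)>soft_floor) continue;
      double dz=xyz(i,2)-xyz(j,2);
      double d2=dx*dx+dy*dy+dz*dz;
      if(d2<soft_floor*soft_floor){
        double d=sqrt(d2);
        if(d<mind) mind=d;
        double v=soft_floor-d; pen+=v*v;
      }
    }
  }
  return List::create(_["rg"]=rg,_["pen"]=pen,_["min_nonbonded"]=mind);
}
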