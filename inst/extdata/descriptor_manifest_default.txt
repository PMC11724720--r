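ATSe1
ATSe2
ATSe3
ATSe4
ATSe5
ATSe6
ATSe7
ATSe8
ATSm1
ATSm2
ATSm3
ATSm4
ATSm5
ATSm6
ATSm7
ATSm8
ATSp1
ATSp2
ATSp3
ATSp4
ATSp5
ATSp6
ATSp7
ATSp8
ATSv1
ATSv2
ATSv3
ATSv4
ATSv5
ATSv6
ATSv7
ATSv8
BalabanJ
Chi0
Chi0v
Chi1
Chi1v
Chi2
Chi2v
Chi3
Chi3v
Chi4
Chi4v
EStateMax
EStateMean
EStateMin
EStateSum
EccentricConnectivity
GATSe1
GATSe2
GATSe3
GATSe4
GATSe5
GATSe6
GATSe7
GATSe8
GATSm1
GATSm2
GATSm3
GATSm4
GATSm5
GATSm6
GATSm7
GATSm8
GATSp1
GATSp2
GATSp3
GATSp4
GATSp5
GATSp6
GATSp7
GATSp8
GATSv1
GATSv2
GATSv3
GATSv4
GATSv5
GATSv6
GATSv7
GATSv8
HararyIndex
Kappa1
Kappa2
Kappa3
MATSe1
MATSe2
MATSe3
MATSe4
MATSe5
MATSe6
MATSe7
MATSe8
MATSm1
MATSm2
MATSm3
MATSm4
MATSm5
MATSm6
MATSm7
MATSm8
MATSp1
MATSp2
MATSp3
MATSp4
MATSp5
MATSp6
MATSp7
MATSp8
MATSv1
MATSv2
MATSv3
MATSv4
MATSv5
MATSv6
MATSv7
MATSv8
MolecularFlexibility
OB_HBA1
OB_HBA2
OB_HBD
OB_MR
OB_MW
OB_TPSA
OB_logP
OB_nF
PetitjeanIndex
PlattIndex
TotalWalkCount2
TotalWalkCount3
WienerIndex
WienerPolarity
ZagrebM1
ZagrebM2
avgAtomicMass
fracC
fracHetero
fracN
fracO
fracRingAtoms
graphDensity
graphDiameter
graphRadius
longestCarbonChain
meanBondOrder
meanDegree
meanDistance
meanEccentricity
nAcyclicAtoms
nAmide
nAromaticAtoms
nAromaticRings
nAtomBr
nAtomC
nAtomCl
nAtomF
nAtomI
nAtomN
nAtomO
nAtomP
nAtomS
nBonds
nBondsBridge
nBondsDouble
nBondsRing
nBondsRotatable
nBondsSingle
nBondsTriple
nCarbonyl
nCarboxyl
nDeg1
nDeg2
nDeg3
nDeg4
nEther
nHalogen
nHeavyAtoms
nHetero
nHydroxyl
nImplicitH
nMethoxy
nNitrile
nPrimaryAmine
nRingAtoms
nRingsSSSR
nTerminalAtoms
totalPolarizability
totalValence
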