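species,low,high,rank_group,note
0,250000,1000000,1,PI is the dominant inner-leaflet inositol lipid reservoir
4,5000,20000,2,PI4P pool roughly similar to the PIP2 pool
45,5000,20000,2,PIP2 around 10000 molecules per um^2
3,250,1000,3,plasma-membrane PI3P is a small pool
5,100,600,3,PI5P is a small pool
34,50,300,3,PI34P2 is a small signalling pool
35,10,100,4,PI35P2 is scarce at the plasma membrane
345,2,100,4,PIP3 is scarce outside stimulation
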