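cell_id,sample_id,x_um,y_um,nuclear_area_um2,DAPI,PanCK,CD45,CD4
c1,core_01,10.5,20.25,45.2,512.3,310.1,12.4,9.8
c2,core_01,30.0,22.75,52.8,488.9,15.2,280.4,295.6
c3,core_02,5.25,8.5,38.1,530.2,18.7,250.3,11.2
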