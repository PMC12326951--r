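Frame 1
0,0,0,0,0,0,0,0,0,0,0,0
0,0,0,0,0,0,0,0,0,0,0,0
0,0,0,0,0,0,0,0,0,0,0,0
0,0,0,0,0,0,0,0,0,0,0,0
0,0,0,0,129.8,107.2,106.2,123.1,0,0,0,0
0,0,0,101.9,68.6,83.5,83,71.4,110.9,0,0,0
0,0,0,116.6,66,75.4,81.8,79.3,135.5,0,0,0
0,0,0,114.7,68.8,45.9,48.3,84.2,105.6,0,0,0
0,0,0,115.3,75.8,44.3,43.4,74.2,118.4,0,0,0
0,0,0,127.9,75,47.6,53.2,67,91.2,0,0,0
0,0,0,101.2,71.7,62.6,80.5,80,112.5,0,0,0
0,0,0,0,104,109,123,123.7,0,0,0,0
0,0,0,0,0,0,0,0,0,0,0,0
0,0,0,0,0,0,0,0,0,0,0,0
0,0,0,0,0,0,0,0,0,0,0,0
0,0,0,0,0,0,0,0,0,0,0,0

Frame 2
0,0,0,0,0,0,0,0,0,0,0,0
0,0,0,0,0,0,0,0,0,0,0,0
0,0,0,0,0,0,0,0,0,0,0,0
0,0,0,0,0,0,0,0,0,0,0,0
0,0,0,0,302.9,250.1,247.8,287.2,0,0,0,0
0,0,0,237.8,160.1,194.9,193.7,166.5,258.7,0,0,0
0,0,0,272.1,154,175.9,190.8,185.1,316.3,0,0,0
0,0,0,267.7,160.5,107.1,112.6,196.4,246.5,0,0,0
0,0,0,269.1,176.9,103.3,101.3,173.1,276.3,0,0,0
0,0,0,298.4,175.1,111.2,124.2,156.4,212.8,0,0,0
0,0,0,236.2,167.2,146,187.8,186.7,262.6,0,0,0
0,0,0,0,242.6,254.2,287,288.7,0,0,0,0
0,0,0,0,0,0,0,0,0,0,0,0
0,0,0,0,0,0,0,0,0,0,0,0
0,0,0,0,0,0,0,0,0,0,0,0
0,0,0,0,0,0,0,0,0,0,0,0

Frame 3
0,0,0,0,0,0,0,0,0,0,0,0
0,0,0,0,0,0,0,0,0,0,0,0
0,0,0,0,0,0,0,0,0,0,0,0
0,0,0,0,0,0,0,0,0,0,0,0
0,0,0,0,432.7,357.3,354,410.4,0,0,0,0
0,0,0,339.7,228.7,278.5,276.7,237.8,369.6,0,0,0
0,0,0,388.8,220,251.3,272.6,264.4,451.8,0,0,0
0,0,0,382.4,229.3,153,160.9,280.6,352.1,0,0,0
0,0,0,384.5,252.7,147.5,144.7,247.3,394.7,0,0,0
0,0,0,426.3,250.1,158.8,177.4,223.4,303.9,0,0,0
0,0,0,337.5,238.9,208.6,268.3,266.7,375.1,0,0,0
0,0,0,0,346.6,363.2,410,412.4,0,0,0,0
0,0,0,0,0,0,0,0,0,0,0,0
0,0,0,0,0,0,0,0,0,0,0,0
0,0,0,0,0,0,0,0,0,0,0,0
0,0,0,0,0,0,0,0,0,0,0,0

Frame 4
0,0,0,0,0,0,0,0,0,0,0,0
0,0,0,0,0,0,0,0,0,0,0,0
0,0,0,0,0,0,0,0,0,0,0,0
0,0,0,0,0,0,0,0,0,0,0,0
0,0,0,0,346.2,285.8,283.2,328.3,0,0,0,0
0,0,0,271.8,183,222.8,221.4,190.3,295.7,0,0,0
0,0,0,311,176,201.1,218.1,211.5,361.4,0,0,0
0,0,0,305.9,183.5,122.4,128.7,224.5,281.7,0,0,0
0,0,0,307.6,202.1,118,115.7,197.9,315.8,0,0,0
0,0,0,341,200.1,127.1,141.9,178.7,243.2,0,0,0
0,0,0,270,191.1,166.8,214.6,213.4,300.1,0,0,0
0,0,0,0,277.3,290.6,328,329.9,0,0,0,0
0,0,0,0,0,0,0,0,0,0,0,0
0,0,0,0,0,0,0,0,0,0,0,0
0,0,0,0,0,0,0,0,0,0,0,0
0,0,0,0,0,0,0,0,0,0,0,0

Frame 5
0,0,0,0,0,0,0,0,0,0,0,0
0,0,0,0,0,0,0,0,0,0,0,0
0,0,0,0,0,0,0,0,0,0,0,0
0,0,0,0,0,0,0,0,0,0,0,0
0,0,0,0,173.1,142.9,141.6,164.1,0,0,0,0
0,0,0,135.9,91.5,111.4,110.7,95.1,147.8,0,0,0
0,0,0,155.5,88,100.5,109,105.8,180.7,0,0,0
0,0,0,152.9,91.7,61.2,64.4,112.2,140.8,0,0,0
0,0,0,153.8,101.1,59,57.9,98.9,157.9,0,0,0
0,0,0,170.5,100.1,63.5,70.9,89.4,121.6,0,0,0
0,0,0,135,95.6,83.4,107.3,106.7,150,0,0,0
0,0,0,0,138.6,145.3,164,165,0,0,0,0
0,0,0,0,0,0,0,0,0,0,0,0
0,0,0,0,0,0,0,0,0,0,0,0
0,0,0,0,0,0,0,0,0,0,0,0
0,0,0,0,0,0,0,0,0,0,0,0

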