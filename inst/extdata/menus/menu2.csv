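food,group,grams,carbohydrate_g_100g,fiber_g_100g,fat_g_100g,sfa_g_100g,protein_g_100g,sodium_mg_100g
brown rice (cooked),cereals,200,25,1.8,1,0.3,2.6,3
rye bread,cereals,100,45,6.5,1.5,0.3,7.5,500
olive oil,fats and oils,30,0,0,100,14,0,0
semi-skimmed milk,milk and dairy products,300,4.8,0,1.6,1,3.3,45
dark chocolate,"sugars, sweets and pastries",15,45,7,31,18,5,20
coffee with sugar,beverages,150,4,0,0.1,0,0.2,2
lentils (cooked),legumes,200,17,7.9,0.5,0.1,9,5
grilled sardines,fish,110,0,0,9,2.5,20,120
banana,fruits and nuts,150,20,2.6,0.3,0.1,1.1,1
walnuts,fruits and nuts,20,7,6.7,65,6.1,15,2
spinach salad,vegetables,250,3.5,2.2,0.4,0.1,2.8,70
turkey slices,meat and meat products,60,1,0,2,0.6,18,600
boiled egg,eggs,50,0.7,0,10,3,12.5,140
vegetable broth,miscellaneous,200,1,0.3,0.5,0.1,0.5,180
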