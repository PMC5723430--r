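item_id,name,kind,attached_to,serv_small_g,serv_med_g,serv_large_g,carb_g,protein_g,fat_g,sugars_g,fiber_g,sodium_mg
fruit_fresh,Fresh fruit,food,,70,140,280,13,0.7,0.3,10,2.2,1
veg_raw,Vegetables raw or cooked,food,,60,120,240,6,1.8,0.3,3,2.5,30
rice_cooked,Rice and other cooked grains,food,,90,180,270,28,2.7,0.3,0.1,0.4,1
oatmeal,Oatmeal cooked,food,,120,240,360,12,2.5,1.5,0.3,1.7,4
beans,Beans and lentils,food,,85,170,255,21,8,0.5,0.3,7,2
nuts,Nuts and seeds,food,,15,30,60,20,20,50,4,8,5
chicken,Chicken or turkey,food,,85,140,200,0,27,7,0,0,75
fish,Fish baked or grilled,food,,85,140,200,0,22,6,0,0,60
eggs,Eggs,food,,50,100,150,1,13,10,1,0,140
salad,Green salad,food,,50,100,200,3,1.2,0.2,1.5,1.5,15
milk,Milk plain,beverage,,120,240,360,5,3.3,3.3,5,0,45
coffee,Coffee or tea,beverage,,180,240,480,0.2,0.1,0,0,0,2
juice100,100 percent fruit juice,beverage,,120,240,360,10,0.5,0.2,9,0.2,2
sugar_added,Sugar or honey added to beverages,condiment,coffee,4,8,12,100,0,0,100,0,0
butter,Butter,condiment,bread,5,10,20,0.1,0.9,81,0.1,0,650
cheese,Cheese,food,,28,56,84,2,25,33,1,0,650
canned_veg,Canned vegetables,food,,80,160,240,5,1.5,0.3,2.5,1.8,280
canned_fruit,Canned fruit in syrup,food,,80,160,240,19,0.4,0.1,18,1,5
ham,Ham and other cured meats,food,,56,85,140,1.5,18,9,1,0,1100
soda,Soft drinks regular,beverage,,240,360,600,11,0,0,11,0,4
fruit_drink,Fruit-flavored drinks,beverage,,240,360,480,12,0.1,0,11.5,0,15
bread,Bread rolls and buns,food,,25,50,100,49,9,4,5,2.7,490
cereal,Breakfast cereal,food,,30,45,60,84,7,2,30,3,500
cake,Cakes cookies and pies,food,,40,80,120,55,5,18,35,1.2,330
chips,Potato chips and salty snacks,food,,28,50,85,53,7,34,2,4,530
candy,Candy and chocolate,food,,20,40,60,60,5,30,52,2,70
icecream,Ice cream,food,,65,130,195,24,3.5,11,21,0.5,80
pizza,Pizza and ready-to-heat dishes,food,,100,200,300,30,11,10,3.5,2,600
hotdog,Hot dogs and reconstituted meats,food,,50,100,150,3,12,26,1.5,0,900
yogurt_sweet,Sweetened and flavored yogurt,food,,113,170,227,16,4,2.5,15,0,60
margarine,Margarine and spreads,condiment,bread,5,10,20,0.5,0.2,60,0.5,0,700
dressing,Salad dressing,condiment,salad,15,30,45,10,1,40,8,0.3,900
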